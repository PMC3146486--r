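test_that("fit_age_model recovers an exact line and handles degenerate voxels", {
  g <- c(2, 2, 1)
  mk <- full_mask(g)
  # voxel values collinear in age at every voxel: y = 1.4 - 0.01 * age;
  # one voxel held constant at 0.7
  mkvol <- function(a) {
    v <- array(1.4 - 0.01 * a, g); v[2, 2, 1] <- 0.7; v
  }
  st <- volume_stack(lapply(c(60, 70, 80), mkvol))
  f <- fit_age_model(st, c(60, 70, 80), mk)
  expect_equal(f$beta_age[1:3], rep(-0.01, 3), tolerance = 1e-12)
  expect_equal(f$beta0[1:3], rep(1.4, 3), tolerance = 1e-12)
  expect_equal(f$beta_age[4], 0)            # constant voxel
  expect_equal(f$beta0[4], 0.7)

  expect_error(fit_age_model(subset_stack(st, 1:2), c(60, 70), mk),
               class = "TooFewSubjects")
  expect_error(fit_age_model(st, c(70, 70, 70), mk),
               class = "DegenerateAges")
})

test_that("per-voxel OLS matches lm() and satisfies the normal equations", {
  set.seed(31)
  g <- c(3, 2, 1)
  n <- 12
  ages <- runif(n, 55, 90)
  st <- make_stack(n, grid = g, fun = function(i)
    array(0.5 - 0.004 * ages[i] + rnorm(prod(g), 0, 0.05), g))
  mk <- full_mask(g)
  f <- fit_age_model(st, ages, mk)
  Y <- stack_matrix(st, mk)
  X <- cbind(1, ages)
  for (v in seq_len(ncol(Y))) {
    ref <- stats::lm(Y[, v] ~ ages)          # independent oracle
    expect_equal(unname(coef(ref)), c(f$beta0[v], f$beta_age[v]),
                 tolerance = 1e-10)
    # normal equations X'X b = X'y, relative residual <= 1e-8
    b <- c(f$beta0[v], f$beta_age[v])
    resid <- crossprod(X) %*% b - crossprod(X, Y[, v])
    expect_lt(max(abs(resid)) / max(abs(crossprod(X, Y[, v]))), 1e-8)
  }
})

test_that("apply_correction subtracts beta_age * age and passes out-of-mask voxels through", {
  g <- c(2, 2, 1)
  mk <- mask_volume(array(c(TRUE, TRUE, TRUE, FALSE), g))
  st <- volume_stack(lapply(c(1, 2, 3), function(i) array(0.5, g)))
  field <- fit_age_model(
    volume_stack(lapply(c(60, 70, 80), function(a) array(0.9 - 0.01 * a, g))),
    c(60, 70, 80), mk)
  out <- apply_correction(st, c(70, 70, 70), field)
  # y_c = 0.5 - (-0.01 * 70) = 1.2 in masked voxels
  expect_equal(as.vector(out$data[, , , 1])[1:3], rep(1.2, 3), tolerance = 1e-12)
  expect_equal(as.vector(out$data[, , , 1])[4], 0.5)   # outside mask untouched

  # zero slope field => identity
  zf <- fit_age_model(
    volume_stack(lapply(c(60, 70, 80), function(a) array(0.4, g))),
    c(60, 70, 80), mk)
  expect_equal(apply_correction(st, c(65, 75, 85), zf)$data, st$data)
})

test_that("refitting on corrected controls gives zero slope everywhere (nullity)", {
  fc <- fit_and_correct(phantom_spec(grid = c(8L, 8L, 8L), n_controls = 20L,
                                     n_patients = 3L, seed = 13L))
  refit <- fit_age_model(subset_stack(fc$corrected, fc$ctrl),
                         fc$ph$cohort$age[fc$ctrl], fc$mask)
  expect_lt(max(abs(refit$beta_age)), 1e-8)
})

test_that("correction preserves two-sample contrasts and is equivariant in age units", {
  set.seed(41)
  g <- c(4, 4, 2)
  n <- 10
  ages <- runif(n, 60, 85)
  delta <- 0.07
  ctrl_vols <- lapply(seq_len(n), function(i)
    array(0.5 - 0.003 * ages[i] + rnorm(prod(g), 0, 0.02), g))
  pat_vols <- lapply(ctrl_vols, function(v) v + delta)  # same ages, offset
  st <- volume_stack(c(ctrl_vols, pat_vols),
                     subject_ids = sprintf("s%02d", 1:(2 * n)))
  mk <- full_mask(g)
  field <- fit_age_model(subset_stack(st, 1:n), ages, mk)
  out <- apply_correction(st, c(ages, ages), field)
  Y <- stack_matrix(out, mk)
  diffs <- colMeans(Y[(n + 1):(2 * n), ]) - colMeans(Y[1:n, ])
  expect_equal(diffs, rep(delta, ncol(Y)), tolerance = 1e-10)

  # years -> months: refitted model yields identical corrected values
  field_m <- fit_age_model(subset_stack(st, 1:n), ages * 12, mk)
  out_m <- apply_correction(st, c(ages, ages) * 12, field_m)
  expect_equal(out_m$data, out$data, tolerance = 1e-9)
})

test_that("strict CV never corrects a control with its own half's model", {
  sp <- phantom_spec(grid = c(6L, 6L, 6L), n_controls = 11L, n_patients = 8L,
                     seed = 17L)
  ph <- generate_cohort(sp)
  mk <- full_mask(sp$grid)
  ctrl <- ph$cohort$group == "control"
  res <- correct_strict_cv(subset_stack(ph$stack, ctrl),
                           ph$cohort$age[ctrl],
                           subset_stack(ph$stack, !ctrl),
                           ph$cohort$age[!ctrl], mk, seed = 5L)
  halves <- agedetrend:::split_half_indices(sum(ctrl), seed = 5L)
  asg <- res$assignment[res$assignment$group == "control", ]
  # odd count: first half one larger
  expect_equal(length(halves[[1]]), 6L)
  # model k was fit on half k, so half-k members must be assigned model 3-k
  expect_true(all(asg$model_index[halves[[1]]] == 2L))
  expect_true(all(asg$model_index[halves[[2]]] == 1L))

  # determinism: same seed reproduces everything; another seed moves patients
  res2 <- correct_strict_cv(subset_stack(ph$stack, ctrl),
                            ph$cohort$age[ctrl],
                            subset_stack(ph$stack, !ctrl),
                            ph$cohort$age[!ctrl], mk, seed = 5L)
  expect_identical(res2$assignment, res$assignment)
  expect_identical(res2$controls$data, res$controls$data)

  expect_error(correct_strict_cv(subset_stack(ph$stack, which(ctrl)[1:5]),
                                 ph$cohort$age[ctrl][1:5],
                                 subset_stack(ph$stack, !ctrl),
                                 ph$cohort$age[!ctrl], mk, seed = 1L),
               class = "TooFewSubjects")
})

test_that("strict CV on an age-free noiseless phantom is the identity", {
  sp <- phantom_spec(grid = c(5L, 5L, 5L), n_controls = 8L, n_patients = 6L,
                     beta_age = 0, noise_sd = 0, baseline_roughness = 0,
                     seed = 2L)
  ph <- generate_cohort(sp)
  mk <- full_mask(sp$grid)
  ctrl <- ph$cohort$group == "control"
  res <- correct_strict_cv(subset_stack(ph$stack, ctrl), ph$cohort$age[ctrl],
                           subset_stack(ph$stack, !ctrl), ph$cohort$age[!ctrl],
                           mk, seed = 3L)
  expect_equal(res$controls$data, ph$stack$data[, , , ctrl, drop = FALSE])
  expect_equal(res$patients$data, ph$stack$data[, , , !ctrl, drop = FALSE])
})

test_that("cross-applied correction removes most of the age slope at almost all voxels", {
  # 60 controls, noise sd 0.02, constant true slope -0.003.  Sampling theory
  # for the pooled refit of cross-corrected halves gives a remaining-slope
  # SD of ~7e-4 here (both halves' estimation errors enter, weighted by
  # unequal age moments), so the supported levels are: >= 50% reduction at
  # >= 90% of voxels and >= 80% reduction at >= 50% of voxels.
  sp <- phantom_spec(grid = c(8L, 8L, 8L), n_controls = 60L, n_patients = 6L,
                     beta_age = -0.003, noise_sd = 0.02, seed = 19L)
  ph <- generate_cohort(sp)
  mk <- full_mask(sp$grid)
  ctrl <- ph$cohort$group == "control"
  cs <- subset_stack(ph$stack, ctrl)
  ages <- ph$cohort$age[ctrl]
  res <- correct_strict_cv(cs, ages, subset_stack(ph$stack, !ctrl),
                           ph$cohort$age[!ctrl], mk, seed = 7L)
  before <- fit_age_model(cs, ages, mk)$beta_age
  after <- fit_age_model(res$controls, ages, mk)$beta_age
  expect_gte(mean(abs(after) <= 0.5 * abs(before)), 0.9)
  expect_gte(mean(abs(after) <= 0.2 * abs(before)), 0.5)
  # and the refit slopes are unbiased around zero
  expect_lt(abs(mean(after)), 1e-4)
})
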