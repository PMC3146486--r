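test_that("glm_t_map matches an explicit normal-equations oracle and the pooled t", {
  set.seed(51)
  g <- c(2, 2, 1)
  n <- 6
  group <- factor(rep(c("control", "patient"), each = 3),
                  levels = c("control", "patient"))
  covar <- c(0.2, -1, 0.5, 1.2, 0, -0.7)
  st <- make_stack(n, grid = g, fun = function(i) array(rnorm(4), g))
  mk <- full_mask(g)
  des <- vbm_design(group, cov1 = covar)
  sm <- glm_t_map(st, des, mk)
  expect_equal(sm$df, n - 3L)

  Y <- stack_matrix(st, mk)
  X <- des$X
  XtXinv <- solve(t(X) %*% X)                # brute-force oracle
  for (v in seq_len(ncol(Y))) {
    b <- XtXinv %*% t(X) %*% Y[, v]
    r <- Y[, v] - X %*% b
    s2 <- sum(r^2) / (n - 3)
    t_ref <- (des$contrast %*% b) / sqrt(s2 * t(des$contrast) %*% XtXinv %*% des$contrast)
    expect_equal(sm$t[v], as.numeric(t_ref), tolerance = 1e-10)
  }

  # without covariates the map equals the classical pooled two-sample t
  des0 <- vbm_design(group)
  sm0 <- glm_t_map(st, des0, mk)
  for (v in seq_len(ncol(Y))) {
    a <- Y[1:3, v]; b <- Y[4:6, v]
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
    expect_equal(sm0$t[v], t_ref, tolerance = 1e-10)
  }

  # identical groups: t = 0 everywhere
  same <- make_stack(n, grid = g, fun = function(i) array(0.4, g))
  expect_true(all(glm_t_map(same, des0, mk)$t == 0))
})

test_that("rank deficiency and exhausted df are contract violations", {
  g <- c(2, 2, 1)
  st <- make_stack(4, grid = g, fun = function(i) array(rnorm(4), g))
  mk <- full_mask(g)
  group <- factor(c("a", "a", "b", "b"))
  dup <- vbm_design(group, c1 = c(1, 1, 0, 0))  # duplicates the group column
  expect_error(glm_t_map(st, dup, mk), class = "RankDeficient")
  # two controls only: df <= 0 in the age correlation
  two <- subset_stack(st, 1:2)
  expect_error(age_correlation_map(two, c(60, 70), mask = mk),
               class = "RankDeficient")
})

test_that("age correlation is calibrated under the null and localized under a planted slope", {
  set.seed(61)
  # null: 200 noise-only datasets on a 12^3 grid, one-tailed p<0.001 threshold
  g <- c(12L, 12L, 12L)
  mk <- full_mask(g)
  n <- 20
  exceed <- 0; total <- 0
  for (rep in 1:200) {
    ages <- runif(n, 60, 90)
    st <- volume_stack(array(rnorm(prod(g) * n), dim = c(g, n)))
    sm <- age_correlation_map(st, ages, mask = mk)
    exceed <- exceed + sum(sm$t >= qt(0.999, sm$df))
    total <- total + length(sm$t)
  }
  frac <- exceed / total
  ci_half <- 1.96 * sqrt(0.001 * 0.999 / total)
  # correlated voxels within a dataset widen the effective CI a little; the
  # voxels here are independent by construction so the binomial CI applies
  expect_gt(frac, 0.001 - 3 * ci_half)
  expect_lt(frac, 0.001 + 3 * ci_half)

  # planted negative slope region concentrates negative t there
  sp <- vbm_scenario_spec(0, seed = 3L, n_controls = 40L, n_patients = 3L)
  ph <- generate_cohort(sp)
  mkf <- full_mask(sp$grid)
  ctrl <- ph$cohort$group == "control"
  sm <- age_correlation_map(subset_stack(ph$stack, ctrl),
                            ph$cohort$age[ctrl],
                            sex = ph$cohort$sex[ctrl], mask = mkf)
  core <- as.vector(ph$truth$beta_field < -0.0025)
  far <- as.vector(abs(ph$truth$beta_field) < 1e-5)  # beyond the smooth edge
  expect_lt(mean(sm$t[core]), -3)
  expect_lt(abs(mean(sm$t[far])), 0.5)
})

test_that("cluster labeling agrees with a flood-fill oracle for all connectivities", {
  set.seed(71)
  for (i in 1:6) {
    flag <- array(runif(10^3) < 0.3, c(10, 10, 10))
    for (conn in c(6L, 18L, 26L)) {
      ours <- label_clusters(flag, conn)
      ref <- flood_fill_labels(flag, conn)
      expect_true(same_partition(ours$labels, ref))
      expect_equal(sort(ours$sizes, decreasing = TRUE),
                   sort(as.vector(table(ref[ref > 0])), decreasing = TRUE))
    }
  }
  # empty input
  none <- label_clusters(array(FALSE, c(3, 3, 3)))
  expect_equal(none$sizes, integer(0))
})

test_that("cluster_fwe finds a planted blob, returns empty reports gracefully, and is seed-stable", {
  set.seed(81)
  g <- c(12L, 12L, 12L)
  mk <- full_mask(g)
  n <- 24
  group <- factor(rep(c("control", "patient"), each = n / 2),
                  levels = c("control", "patient"))
  sigma <- 0.02
  blob <- region_mask(region_spec("sphere", center = c(5, 5, 5), radius = 2.9),
                      g)  # ~100 voxels
  # patients lose 3 sigma inside the blob
  vols <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(g), 0.5, sigma), g)
    if (group[i] == "patient") v[blob] <- v[blob] - 3 * sigma
    v
  })
  st <- volume_stack(vols)
  des <- vbm_design(group)
  rep1 <- cluster_fwe(st, des, mk, voxel_p = 0.001, n_perm = 500, seed = 9L)
  expect_gte(nrow(rep1), 1)
  expect_true(rep1$significant[1])
  expect_lte(rep1$p_fwe[1], 0.05)
  expect_gte(rep1$size[1], 50)

  rep2 <- cluster_fwe(st, des, mk, voxel_p = 0.001, n_perm = 500, seed = 9L)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  # all-null map: empty report, not an error
  null_st <- volume_stack(array(rnorm(prod(g) * n, 0.5, sigma), c(g, n)))
  rep0 <- cluster_fwe(null_st, des, mk, voxel_p = 1e-9, n_perm = 100, seed = 1L)
  expect_equal(nrow(rep0), 0)
})

test_that("age-as-covariate equals corrected-inputs when the analysed set is the fitting set", {
  # Frisch-Waugh equivalence: identical age vectors in both groups (group
  # orthogonal to age), the fit pooled over ALL analysed subjects, and df
  # adjusted for the pre-regression slope
  set.seed(91)
  g <- c(4, 4, 2)
  n2 <- 9
  ages <- runif(n2, 60, 85)
  st <- make_stack(2 * n2, grid = g, fun = function(i)
    array(0.5 - 0.004 * c(ages, ages)[i] + rnorm(prod(g), 0, 0.03), g))
  mk <- full_mask(g)
  group <- factor(rep(c("control", "patient"), each = n2),
                  levels = c("control", "patient"))

  des_b <- vbm_design(group, age = c(ages, ages))
  t_b <- glm_t_map(st, des_b, mk)

  field <- fit_age_model(st, c(ages, ages), mk)   # pooled fitting set
  corr <- apply_correction(st, c(ages, ages), field)
  des_c <- vbm_design(group)
  t_c <- glm_t_map(corr, des_c, mk, df_adjust = 1L)

  expect_equal(t_b$df, t_c$df)
  expect_equal(t_b$t, t_c$t, tolerance = 1e-8)

  # ... and the regimes genuinely differ on a confounded phantom with the
  # control-only fit
  fc <- fit_and_correct(vbm_scenario_spec(-10, seed = 7L, n_controls = 20L,
                                          n_patients = 12L))
  grp <- factor(fc$ph$cohort$group, levels = c("control", "patient"))
  t_cov <- glm_t_map(fc$ph$stack, vbm_design(grp, age = fc$ph$cohort$age), fc$mask)
  t_pre <- glm_t_map(fc$corrected, vbm_design(grp), fc$mask, df_adjust = 1L)
  expect_gt(max(abs(t_cov$t - t_pre$t)), 0.1)
})
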