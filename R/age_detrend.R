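# Control-only voxel-wise linear age correction.
#
# At every in-mask voxel an ordinary-least-squares line
#   y = beta0 + beta_age * age + eps
# is fitted over HEALTHY CONTROLS ONLY (fitting on patients could absorb
# disease-related change that interacts with age), and the age-explained
# component beta_age * age_i is then subtracted from every subject's value,
# patients included.  Subtraction uses uncentered age, exactly as stated by
# the corrected-value formula; this shifts all subjects by a voxel-wise
# constant relative to mean-centred subtraction and is immaterial for
# two-sample contrasts (a `center_age` option provides the alternative).
#
# The closed-form two-parameter OLS solution is used per voxel, vectorised
# across the mask: with centred ages ac = a - mean(a),
#   beta_age = sum(ac * y) / sum(ac^2),  beta0 = mean(y) - beta_age * mean(a).

#' Fit the per-voxel linear age model on controls
#'
#' @param controls `volume_stack` of control subjects.
#' @param ages Numeric vector of control ages (years), aligned to the stack.
#' @param mask `mask_volume` on the same grid.
#' @return An `age_model_field`: per-voxel intercept (`beta0`) and slope
#'   (`beta_age`) vectors over the mask, plus `n_fit`, `age_mean_fit`, the
#'   mask and grid metadata.
#' @export
fit_age_model <- function(controls, ages, mask) {
  n <- n_subjects(controls)
  if (length(ages) != n) stop("ages length must match number of control volumes")
  if (n < 3L) stop_too_few_subjects(sprintf("need >= 3 controls to fit, got %d", n))
  if (stats::var(ages) == 0) stop_degenerate_ages("control ages have zero variance")
  check_stack_grid(controls, dim(mask$data), what = "mask")

  Y <- stack_matrix(controls, mask)             # n x V
  ac <- ages - mean(ages)
  sxx <- sum(ac^2)
  beta_age <- as.vector(crossprod(ac, Y)) / sxx # colSums(ac * Y)
  beta0 <- colMeans(Y) - beta_age * mean(ages)
  # degenerate voxels (zero variance across controls): slope 0, intercept mean
  degen <- apply(Y, 2, function(col) all(col == col[1]))
  if (any(degen)) {
    beta_age[degen] <- 0
    beta0[degen] <- Y[1, degen]
  }
  structure(list(beta0 = beta0, beta_age = beta_age, n_fit = n,
                 age_mean_fit = mean(ages), mask = mask,
                 shape = grid_shape(controls), affine = controls$affine),
            class = "age_model_field")
}

#' @export
print.age_model_field <- function(x, ...) {
  cat(sprintf("AgeModelField: %d voxels, fitted on %d controls (mean age %.1f y)\n",
              length(x$beta_age), x$n_fit, x$age_mean_fit))
  cat(sprintf("  beta_age range: [%.3g, %.3g] per year\n",
              min(x$beta_age), max(x$beta_age)))
  invisible(x)
}

#' Remove the age-explained component from a stack
#'
#' Corrected value `y_c = y - beta_age * age_i` at every in-mask voxel
#' (optionally `beta_age * (age_i - age_mean_fit)` when `center_age`);
#' voxels outside the mask pass through unchanged.  Applied to controls and
#' patients alike.  Corrected values are not clipped to be nonnegative.
#'
#' @param stack `volume_stack` to correct (any group).
#' @param ages Ages aligned to the stack.
#' @param field `age_model_field` from [fit_age_model()].
#' @param center_age Subtract `beta_age * (age - age_mean_fit)` instead of
#'   `beta_age * age`; default `FALSE` (the stated formula).
#' @return Corrected `volume_stack`.
#' @export
apply_correction <- function(stack, ages, field, center_age = FALSE) {
  if (length(ages) != n_subjects(stack)) stop("ages length must match stack")
  check_stack_grid(stack, field$shape, field$affine, what = "age model")
  a <- if (center_age) ages - field$age_mean_fit else ages
  Y <- stack_matrix(stack, field$mask)
  Yc <- Y - outer(a, field$beta_age)
  matrix_to_stack(Yc, like = stack, mask = field$mask)
}

# evaluate expr under a private seeded RNG state; the caller's stream is
# untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

split_half_indices <- function(n, seed = NULL) {
  ord <- if (is.null(seed)) seq_len(n) else with_seed(seed, sample.int(n))
  k <- ceiling(n / 2)                  # odd count: first half gets the extra
  list(ord[seq_len(k)], ord[seq(k + 1L, n)])
}

#' Strictly cross-validated age correction
#'
#' Controls are split into two equal halves (after a seeded shuffle; an odd
#' count puts the extra subject in half 1).  The model fitted on control
#' half k corrects control half 3-k, so no control is ever corrected by a
#' model trained on its own data.  Patients are randomly halved with the
#' same seed and patient half k is corrected by model k.  The model
#' assignment (1 or 2 per subject) is recorded for use as a downstream
#' covariate.
#'
#' @param controls,patients `volume_stack`s.
#' @param control_ages,patient_ages Aligned age vectors.
#' @param mask `mask_volume`.
#' @param seed Integer seed controlling both halvings.
#' @param center_age Passed to [apply_correction()].
#' @return List with corrected `controls` and `patients` stacks, the two
#'   fitted `models`, and `assignment` (data.frame subject_id, group,
#'   model_index).
#' @export
correct_strict_cv <- function(controls, control_ages, patients, patient_ages,
                              mask, seed = 1L, center_age = FALSE) {
  nc <- n_subjects(controls)
  if (nc < 6L) stop_too_few_subjects("strict CV needs >= 6 controls")
  halves_c <- split_half_indices(nc, seed = seed)
  halves_p <- split_half_indices(n_subjects(patients), seed = seed + 1L)

  models <- lapply(1:2, function(k) {
    idx <- halves_c[[k]]
    sub <- volume_stack(controls$data[, , , idx, drop = FALSE],
                        affine = controls$affine,
                        subject_ids = controls$subject_ids[idx])
    fit_age_model(sub, control_ages[idx], mask)
  })

  corr_c <- stack_matrix(controls, mask)
  corr_p <- stack_matrix(patients, mask)
  model_of_control <- integer(nc)
  model_of_patient <- integer(n_subjects(patients))
  for (k in 1:2) {
    other <- 3L - k
    ic <- halves_c[[other]]            # model k corrects the half it never saw
    model_of_control[ic] <- k
    a <- if (center_age) control_ages[ic] - models[[k]]$age_mean_fit else control_ages[ic]
    corr_c[ic, ] <- corr_c[ic, , drop = FALSE] - outer(a, models[[k]]$beta_age)
    ip <- halves_p[[k]]
    model_of_patient[ip] <- k
    ap <- if (center_age) patient_ages[ip] - models[[k]]$age_mean_fit else patient_ages[ip]
    corr_p[ip, ] <- corr_p[ip, , drop = FALSE] - outer(ap, models[[k]]$beta_age)
  }

  assignment <- data.frame(
    subject_id = c(controls$subject_ids, patients$subject_ids),
    group = rep(c("control", "patient"), c(nc, n_subjects(patients))),
    model_index = c(model_of_control, model_of_patient),
    stringsAsFactors = FALSE)

  list(controls = matrix_to_stack(corr_c, like = controls, mask = mask),
       patients = matrix_to_stack(corr_p, like = patients, mask = mask),
       models = models, assignment = assignment, seed = seed)
}
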