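# Split-half SVM classification harness.
#
# The cohort is split into two stratified halves; a linear SVM trained on
# each half classifies the other, and accuracy is the percentage of ALL
# subjects assigned their clinical label across both fold directions.
# Repeating the split with fresh seeds yields accuracy distributions for
# corrected vs uncorrected features, compared by an independent-samples t
# (the repeat-level distributions are not independent across repeats, but
# the independent-samples test is kept as the default to mirror common
# practice; a paired alternative is available).

stratified_halves <- function(labels, seed) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  half1 <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      idx <- idx[sample.int(length(idx))]
      # alternate ceil/floor across classes so half sizes stay balanced
      k <- if (ci %% 2L == 1L) ceiling(length(idx) / 2) else floor(length(idx) / 2)
      half1 <- c(half1, idx[seq_len(k)])
    }
  })
  half1 <- sort(half1)
  half2 <- setdiff(seq_along(labels), half1)
  for (cl in classes) {
    if (!any(labels[half1] == cl) || !any(labels[half2] == cl))
      stop_degenerate_split(sprintf("class '%s' missing from one half", cl))
  }
  list(half1, half2)
}

#' Split-half SVM classification
#'
#' Stratified seeded split into two halves; a linear SVM trained on half 1
#' predicts half 2 and vice versa.  Accuracy is
#' `(correct_1 + correct_2) / n * 100` over all subjects.
#'
#' @param features Subjects x voxels (or features) numeric matrix.
#' @param labels Two-class labels aligned to rows.
#' @param seed Integer seed for the split.
#' @param C SVM cost; default 1.
#' @param standardize Z-score each feature using training-half statistics?
#'   Default `FALSE` (grey-matter maps share units).
#' @return A `classification_result`: per-subject `predicted` labels,
#'   `accuracy` (percent), `fold` assignment (1/2), `seed`.
#' @export
split_half_svm <- function(features, labels, seed = 1L, C = 1,
                           standardize = FALSE) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (length(labels) != n) stop("labels length must match feature rows")
  halves <- stratified_halves(labels, seed)

  predicted <- character(n)
  for (k in 1:2) {
    tr <- halves[[k]]
    te <- halves[[3L - k]]
    Xtr <- features[tr, , drop = FALSE]
    Xte <- features[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sd <- apply(Xtr, 2, stats::sd)
      sd[sd == 0] <- 1
      Xtr <- scale(Xtr, center = mu, scale = sd)
      Xte <- scale(Xte, center = mu, scale = sd)
    }
    fit <- linear_svm(Xtr, labels[tr], C = C)
    predicted[te] <- predict(fit, Xte)
  }
  fold <- integer(n)
  fold[halves[[1]]] <- 1L
  fold[halves[[2]]] <- 2L
  structure(list(predicted = predicted, labels = labels,
                 accuracy = 100 * mean(predicted == labels),
                 fold = fold, seed = seed, C = C,
                 standardize = standardize),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("ClassificationResult: %.1f%% of %d subjects correct (seed %d)\n",
              x$accuracy, length(x$labels), x$seed))
  invisible(x)
}

#' Repeated split-half accuracy for two feature conditions
#'
#' Repeats the split-half SVM `n_repeats` times (repeat r uses seed
#' `seed + r`, the SAME split applied to both conditions) and compares the
#' two accuracy distributions: by default an independent-samples pooled t,
#' optionally a paired t over the shared splits.
#'
#' @param features_uncorrected,features_corrected Subjects x voxels matrices
#'   describing the same subjects in both conditions.
#' @param labels Two-class labels.
#' @param n_repeats Number of repeated splits (>= 2); default 60.
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param paired Use a paired t over the shared splits? Default `FALSE`.
#' @param C,standardize Passed to [split_half_svm()].
#' @return List: `accuracy_uncorrected`, `accuracy_corrected` (numeric
#'   vectors of length `n_repeats`), `t`, `df`, `p_two_tailed`,
#'   `p_one_tailed` (corrected exceeds uncorrected), and the per-condition
#'   means.
#' @export
permutation_accuracy <- function(features_uncorrected, features_corrected,
                                 labels, n_repeats = 60L, seed = 1L,
                                 paired = FALSE, C = 1, standardize = FALSE) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2")
  if (!identical(dim(features_uncorrected)[1], dim(features_corrected)[1]))
    stop("both feature sets must describe the same subjects")
  acc_u <- acc_c <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    s <- seed + r
    acc_u[r] <- split_half_svm(features_uncorrected, labels, seed = s, C = C,
                               standardize = standardize)$accuracy
    acc_c[r] <- split_half_svm(features_corrected, labels, seed = s, C = C,
                               standardize = standardize)$accuracy
  }
  if (paired) {
    d <- acc_c - acc_u
    df <- n_repeats - 1L
    t <- if (stats::sd(d) == 0) 0 else mean(d) / (stats::sd(d) / sqrt(n_repeats))
  } else {
    sp2 <- (stats::var(acc_c) + stats::var(acc_u)) / 2
    df <- 2L * n_repeats - 2L
    t <- if (sp2 == 0) 0 else
      (mean(acc_c) - mean(acc_u)) / sqrt(sp2 * 2 / n_repeats)
  }
  list(accuracy_uncorrected = acc_u, accuracy_corrected = acc_c,
       mean_uncorrected = mean(acc_u), mean_corrected = mean(acc_c),
       t = t, df = df,
       p_two_tailed = 2 * stats::pt(-abs(t), df),
       p_one_tailed = stats::pt(t, df, lower.tail = FALSE),
       paired = paired, n_repeats = n_repeats, seed = seed)
}

#' Age comparison of misclassified subjects
#'
#' Independent-samples t between the ages of misclassified controls and
#' misclassified patients.  The one-tailed p tests the confound direction:
#' misclassified controls OLDER than misclassified patients.
#'
#' @param result A `classification_result`.
#' @param ages Ages aligned to the classified subjects.
#' @param control_label,patient_label Which label plays each role; defaults
#'   `"control"` / `"patient"`.
#' @return List: `t`, `df`, `p_one_tailed`, `p_two_tailed`, group means and
#'   counts of misclassified subjects.
#' @export
misclassified_age_test <- function(result, ages,
                                   control_label = "control",
                                   patient_label = "patient") {
  truth <- result$labels
  mis <- result$predicted != truth
  age_c <- ages[mis & truth == control_label]
  age_p <- ages[mis & truth == patient_label]
  if (length(age_c) == 0L || length(age_p) == 0L ||
      length(age_c) + length(age_p) < 3L) {
    stop_insufficient_misclassifications(
      "need misclassified subjects in both groups (>= 3 total) for the age test")
  }
  df <- length(age_c) + length(age_p) - 2L
  ss <- function(x) if (length(x) < 2L) 0 else (length(x) - 1) * stats::var(x)
  sp2 <- (ss(age_c) + ss(age_p)) / df
  se <- sqrt(sp2 * (1 / length(age_c) + 1 / length(age_p)))
  t <- if (se == 0) 0 else (mean(age_c) - mean(age_p)) / se
  list(t = t, df = df,
       p_one_tailed = stats::pt(t, df, lower.tail = FALSE),
       p_two_tailed = 2 * stats::pt(-abs(t), df),
       mean_age_misclassified_controls = mean(age_c),
       mean_age_misclassified_patients = mean(age_p),
       n_misclassified_controls = length(age_c),
       n_misclassified_patients = length(age_p))
}
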