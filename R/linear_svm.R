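# Linear support-vector machine via SMO on the Gram matrix.
#
# Soft-margin L1-loss SVM,  min_{w,b}  0.5 ||w||^2 + C sum_i xi_i,
# solved in the dual (0 <= alpha_i <= C, sum_i alpha_i y_i = 0) by
# sequential minimal optimization with maximal-violating-pair working-set
# selection — the classic LIBSVM scheme, which keeps the bias unpenalized.
# Selection is deterministic (first maximal index), so training is exactly
# reproducible.  Cohort sizes here are small (n <= a few hundred), so the
# n x n Gram formulation is exact and fast regardless of the voxel count.

#' Train a linear SVM
#'
#' @param X Numeric matrix, subjects x features (finite values).
#' @param y Labels with exactly two classes (factor, character or numeric);
#'   the alphabetically second level is the positive class.
#' @param C Soft-margin cost; default 1.
#' @param tol Stopping tolerance on the maximal KKT violation; default 1e-6.
#' @param max_iter Maximum number of pairwise updates; default 100000.
#' @return Object of class `linear_svm` with weight vector `w`, bias `b`,
#'   dual coefficients `alpha`, and class `levels` (first level = decision
#'   value < 0).
#' @export
linear_svm <- function(X, y, C = 1, tol = 1e-6, max_iter = 100000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite")
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stop("y must have exactly two classes")
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  n <- nrow(X)
  if (length(yy) != n) stop("length(y) must equal nrow(X)")

  K <- tcrossprod(X)
  Q <- K * tcrossprod(yy)
  alpha <- numeric(n)
  G <- rep(-1, n)                       # G = Q alpha - 1
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # maximal violating pair over I_up / I_low
    up <- (yy > 0 & alpha < C - 1e-12) | (yy < 0 & alpha > 1e-12)
    lo <- (yy < 0 & alpha < C - 1e-12) | (yy > 0 & alpha > 1e-12)
    v <- -yy * G
    m_val <- max(v[up]); i <- which(up)[which.max(v[up])]
    M_val <- min(v[lo]); j <- which(lo)[which.min(v[lo])]
    if (m_val - M_val < tol || iter > max_iter) break

    quad <- Q[i, i] + Q[j, j] - 2 * yy[i] * yy[j] * Q[i, j]
    t_star <- (m_val - M_val) / max(quad, 1e-12)
    # clip so alpha_i + y_i t and alpha_j - y_j t stay in [0, C]
    t_max <- min(if (yy[i] > 0) C - alpha[i] else alpha[i],
                 if (yy[j] > 0) alpha[j] else C - alpha[j])
    t_step <- min(t_star, t_max)
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + yy[i] * t_step
    alpha[j] <- alpha[j] - yy[j] * t_step
    G <- G + t_step * (yy[i] * Q[, i] - yy[j] * Q[, j])
  }

  coef <- alpha * yy
  w <- drop(crossprod(X, coef))
  fx <- drop(K %*% coef)                # w . x_i for every subject
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) mean(yy[free] - fx[free]) else {
    # no free support vectors: any b between the active bounds is optimal
    up <- (yy > 0 & alpha < C - 1e-12) | (yy < 0 & alpha > 1e-12)
    lo <- (yy < 0 & alpha < C - 1e-12) | (yy > 0 & alpha > 1e-12)
    v <- -yy * G
    (max(v[up]) + min(v[lo])) / 2
  }
  structure(list(w = w, b = b, alpha = alpha, levels = lev, C = C,
                 iterations = iter),
            class = "linear_svm")
}

#' Predict class labels from a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Subjects x features matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels (decision value >= 0 maps to
#'   the second class level; ties go to the positive class).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  f <- drop(as.matrix(newdata) %*% object$w) + object$b
  ifelse(f >= 0, object$levels[2], object$levels[1])
}

#' Decision values of a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Subjects x features matrix.
#' @return Numeric decision values `w'x + b`.
#' @export
decision_values <- function(object, newdata) {
  drop(as.matrix(newdata) %*% object$w) + object$b
}
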