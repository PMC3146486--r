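# Mass-univariate (VBM-style) inference.
#
# Voxel-wise general linear model t contrasts, the age-correlation analysis
# in controls, and cluster-extent family-wise-error correction.  FWE is
# controlled by PERMUTATION of the maximum suprathreshold cluster size
# (Freedman-Lane scheme under nuisance covariates): exact under
# exchangeability and fully self-contained, replacing parametric
# random-field cluster p-values.

#' Build a two-group design matrix
#'
#' Columns: intercept, group indicator (1 = first level of `group`), then
#' any covariates.  The contrast weights the group column with +1, i.e. a
#' positive t means the first level exceeds the second (atrophy contrasts
#' put controls first).
#'
#' @param group Factor or character vector with exactly two levels.
#' @param ... Named numeric covariates (e.g. `sex = 0/1`, `age`,
#'   `cv_model = 0/1`), each aligned to `group`.
#' @return List with `X` (matrix), `contrast` (vector), `group_levels`.
#' @export
vbm_design <- function(group, ...) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  covs <- list(...)
  X <- cbind(intercept = 1, group = as.numeric(group == levels(group)[1]))
  for (nm in names(covs)) {
    X <- cbind(X, as.numeric(covs[[nm]]))
    colnames(X)[ncol(X)] <- nm
  }
  contrast <- c(0, 1, rep(0, length(covs)))
  list(X = X, contrast = contrast, group_levels = levels(group))
}

# Core vectorised GLM: Y is n x V. Returns per-voxel t and df.
# Voxels with zero residual variance get t = 0 when the contrast effect is
# also zero (flat data), +/-Inf otherwise.
glm_fit_t <- function(Y, X, contrast, df_adjust = 0L) {
  n <- nrow(X)
  if (nrow(Y) != n) stop("design rows must match subjects")
  if (length(contrast) != ncol(X)) stop("contrast length must equal design columns")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_rank_deficient("design matrix is rank deficient")
  df <- n - ncol(X) - df_adjust
  if (df <= 0) stop_rank_deficient(sprintf("no residual degrees of freedom (df = %d)", df))
  XtXinv <- chol2inv(chol(crossprod(X)))
  coef_mat <- XtXinv %*% crossprod(X, Y)          # p x V
  res <- Y - X %*% coef_mat
  sigma2 <- colSums(res^2) / df
  cAc <- drop(t(contrast) %*% XtXinv %*% contrast)
  num <- drop(contrast %*% coef_mat)
  den <- sqrt(sigma2 * cAc)
  t <- num / den
  # numerically zero residual variance: flat data (effect also zero up to
  # rounding) gives t = 0, a genuine effect with no noise gives +/-Inf
  zero <- sigma2 <= 1e-24 * pmax(1, colMeans(Y^2))
  if (any(zero)) {
    tiny <- abs(num[zero]) <= 1e-10 * max(1, max(abs(num)))
    t[zero] <- ifelse(tiny, 0, sign(num[zero]) * Inf)
  }
  list(t = t, df = df)
}

new_stat_map <- function(t, df, mask, shape, affine) {
  structure(list(t = t, df = df, mask = mask, shape = shape, affine = affine),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("StatMap: %d voxels, df = %d, t in [%.2f, %.2f]\n",
              length(x$t), x$df, min(x$t), max(x$t)))
  invisible(x)
}

#' Voxel-wise GLM t-contrast map
#'
#' Per in-mask voxel, `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` with OLS
#' coefficients `b` and residual variance `s2` on `n - rank(X) - df_adjust`
#' degrees of freedom.  `df_adjust` lets the caller account for parameters
#' consumed by a pre-regression (default 0, nominal df).
#'
#' @param stack `volume_stack` of all analysed subjects (groups stacked).
#' @param design A list as from [vbm_design()] (`X` plus `contrast`), or a
#'   bare design matrix if `contrast` is given.
#' @param mask `mask_volume`.
#' @param contrast Optional contrast vector overriding `design$contrast`.
#' @param df_adjust Integer df reduction; default 0.
#' @return A `stat_map` (per-voxel t over the mask, df).
#' @export
glm_t_map <- function(stack, design, mask, contrast = NULL, df_adjust = 0L) {
  X <- if (is.list(design)) design$X else design
  contrast <- contrast %||% design$contrast
  check_stack_grid(stack, dim(mask$data), what = "mask")
  Y <- stack_matrix(stack, mask)
  fit <- glm_fit_t(Y, X, contrast, df_adjust)
  new_stat_map(fit$t, fit$df, mask, grid_shape(stack), stack$affine)
}

#' Voxel-wise age correlation in controls
#'
#' t-map for the age regressor in `y ~ 1 + age + sex`, controls only —
#' the age-related-decline analysis (negative t = loss with age).
#'
#' @param controls `volume_stack` of controls.
#' @param ages Ages aligned to the stack.
#' @param sex Numeric 0/1 covariate (optional).
#' @param mask `mask_volume`.
#' @return A `stat_map`.
#' @export
age_correlation_map <- function(controls, ages, sex = NULL, mask) {
  X <- cbind(intercept = 1, age = ages)
  if (!is.null(sex)) X <- cbind(X, sex = as.numeric(sex))
  contrast <- c(0, 1, if (!is.null(sex)) 0)
  Y <- stack_matrix(controls, mask)
  fit <- glm_fit_t(Y, X, contrast)
  new_stat_map(fit$t, fit$df, mask, grid_shape(controls), controls$affine)
}

connectivity_offsets <- function(connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary volume
#'
#' Maximal connected components under 6 (face), 18 (face+edge, default) or
#' 26 (face+edge+corner) neighbourhoods.
#'
#' @param flag Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer array, 0 = background, components
#'   numbered by decreasing size) and `sizes` (voxel counts per label).
#' @export
label_clusters <- function(flag, connectivity = 18L) {
  shape <- dim(flag)
  labels <- array(0L, dim = shape)
  idx <- which(flag)
  nv <- length(idx)
  if (nv == 0L) return(list(labels = labels, sizes = integer(0)))
  pos <- array(0L, dim = shape)
  pos[idx] <- seq_len(nv)

  parent <- seq_len(nv)
  find_root <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }

  offs <- connectivity_offsets(connectivity)
  # half the offsets suffice: each unordered pair is visited once
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sx <- seq_len(shape[1] - abs(o[1])) + max(0, o[1])
    sy <- seq_len(shape[2] - abs(o[2])) + max(0, o[2])
    sz <- seq_len(shape[3] - abs(o[3])) + max(0, o[3])
    a <- pos[sx, sy, sz, drop = FALSE]
    b <- pos[sx - o[1], sy - o[2], sz - o[3], drop = FALSE]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    va <- a[both]; vb <- b[both]
    for (e in seq_along(va)) {
      ra <- find_root(va[e]); rb <- find_root(vb[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(nv), find_root, 0L)
  comp <- match(roots, unique(roots))
  sizes <- tabulate(comp)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  labels[idx] <- relabel[comp]
  list(labels = labels, sizes = sizes[ord])
}

max_cluster_size <- function(t, tcrit, mask, connectivity, two_tailed = FALSE) {
  flag_vec <- if (two_tailed) abs(t) >= tcrit else t >= tcrit
  if (!any(flag_vec)) return(0L)
  flag <- array(FALSE, dim = dim(mask$data))
  flag[as.logical(mask$data)] <- flag_vec
  cl <- label_clusters(flag, connectivity)
  if (length(cl$sizes) == 0L) 0L else cl$sizes[1]
}

#' Cluster-extent FWE correction by permutation
#'
#' Thresholds the t-map at the one-tailed `voxel_p` quantile of Student's
#' t(df) (two-tailed optional), forms connected suprathreshold clusters, and
#' assigns each a corrected p: the proportion of Freedman-Lane permutations
#' whose MAXIMUM suprathreshold cluster size reaches the observed size.
#' Group labels are permuted as residuals under the nuisance-only reduced
#' model, preserving covariate structure.  A map with no suprathreshold
#' voxel yields an empty report, not an error.
#'
#' @param stack `volume_stack` of analysed subjects.
#' @param design List from [vbm_design()].
#' @param mask `mask_volume`.
#' @param voxel_p Uncorrected voxel-level threshold; default 0.001.
#' @param n_perm Number of permutations (>= 100); default 1000.
#' @param seed Integer seed for the permutation stream.
#' @param connectivity 6, 18 (default) or 26.
#' @param two_tailed Threshold on |t|? Default `FALSE` (directional).
#' @param alpha Cluster-level significance; clusters at `p_fwe < alpha` are
#'   flagged. Default 0.05.
#' @param df_adjust Passed to the GLM (pre-regression df accounting).
#' @return A `cluster_report`: data.frame (cluster_id, size, peak_t, i, j,
#'   k, p_fwe, significant) with threshold metadata in attributes.
#' @export
cluster_fwe <- function(stack, design, mask, voxel_p = 0.001, n_perm = 1000L,
                        seed = 1L, connectivity = 18L, two_tailed = FALSE,
                        alpha = 0.05, df_adjust = 0L) {
  stopifnot(voxel_p > 0, voxel_p < 1)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  X <- design$X
  contrast <- design$contrast
  Y <- stack_matrix(stack, mask)
  fit <- glm_fit_t(Y, X, contrast, df_adjust)
  tcrit <- stats::qt(1 - (if (two_tailed) voxel_p / 2 else voxel_p), fit$df)

  empty <- data.frame(cluster_id = integer(0), size = integer(0),
                      peak_t = numeric(0), i = integer(0), j = integer(0),
                      k = integer(0), p_fwe = numeric(0),
                      significant = logical(0))
  meta <- list(voxel_p = voxel_p, t_threshold = tcrit, df = fit$df,
               n_perm = n_perm, seed = seed, connectivity = connectivity,
               two_tailed = two_tailed, alpha = alpha, df_adjust = df_adjust)

  flag_vec <- if (two_tailed) abs(fit$t) >= tcrit else fit$t >= tcrit
  if (!any(flag_vec)) {
    return(structure(empty, class = c("cluster_report", "data.frame"), meta = meta))
  }
  flag <- array(FALSE, dim = dim(mask$data))
  mask_lin <- which(as.logical(mask$data))
  flag[mask_lin[flag_vec]] <- TRUE
  cl <- label_clusters(flag, connectivity)
  n_cl <- length(cl$sizes)

  # Freedman-Lane: refit under permuted reduced-model residuals
  Z <- X[, contrast == 0, drop = FALSE]
  Zfit <- Z %*% (chol2inv(chol(crossprod(Z))) %*% crossprod(Z, Y))
  Rz <- Y - Zfit
  n <- nrow(Y)
  max_sizes <- integer(n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      Yp <- Zfit + Rz[sample.int(n), , drop = FALSE]
      fp <- glm_fit_t(Yp, X, contrast, df_adjust)
      max_sizes[p] <- max_cluster_size(fp$t, tcrit, mask, connectivity, two_tailed)
    }
  })

  tmap <- array(NA_real_, dim = dim(mask$data))
  tmap[mask_lin] <- fit$t
  rows <- lapply(seq_len(n_cl), function(cid) {
    vox <- which(cl$labels == cid)
    tv <- tmap[vox]
    peak <- vox[which.max(if (two_tailed) abs(tv) else tv)]
    ijk <- arrayInd(peak, dim(mask$data)) - 1L        # 0-based grid coords
    size <- length(vox)
    p_fwe <- (1 + sum(max_sizes >= size)) / (n_perm + 1)
    data.frame(cluster_id = cid, size = size, peak_t = tmap[peak],
               i = ijk[1], j = ijk[2], k = ijk[3], p_fwe = p_fwe,
               significant = p_fwe < alpha)
  })
  rep <- do.call(rbind, rows)
  structure(rep, class = c("cluster_report", "data.frame"), meta = meta)
}

#' @export
print.cluster_report <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("ClusterReport: %d cluster(s) above t = %.2f (voxel p = %g, df = %d), %d permutations\n",
              nrow(x), meta$t_threshold, meta$voxel_p, meta$df, meta$n_perm))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a cluster report as TSV
#'
#' @param report A `cluster_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
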