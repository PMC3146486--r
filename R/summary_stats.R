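# Cohort-characteristics statistics.
#
# Pooled-variance (Student) two-sample t from printed group summaries or raw
# values, Pearson chi-square for independence (no continuity correction),
# and one-way ANOVA with Bonferroni-corrected pairwise post-hocs.  Pooling
# and the absence of the Yates correction are deliberate: published cohort
# tables in this field print df = n_a + n_b - 2 and uncorrected chi-squares,
# and the package reproduces them at printed precision.

#' Summarise a group
#'
#' @param x Raw numeric vector, or `NULL` when giving `n`/`mean`/`sd`.
#' @param n,mean,sd Summary values (sample SD, `n - 1` denominator).
#' @return A `group_summary` (n, mean, sd).
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(x)) {
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (is.null(n) || is.null(mean) || is.null(sd))
    stop("give either raw values x or all of n, mean, sd")
  if (n < 2) stop("group size must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) g else group_summary(x = g)
}

#' Pooled two-sample t-test from group summaries
#'
#' Student t with pooled variance, `df = n_a + n_b - 2`, two-tailed p.
#' When both SDs are zero: t is 0 for equal means (documented convention)
#' and a `ZeroVariance` error otherwise.
#'
#' @param a,b `group_summary` objects (or raw numeric vectors).
#' @return List: `t`, `df`, `p_two_tailed`.
#' @export
t_from_summary <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  if (se == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = df, p_two_tailed = 1))
    stop_zero_variance("both SDs are zero with unequal means; t is undefined")
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p_two_tailed = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; `df = (r - 1)(c - 1)`.
#'
#' @param table r x c matrix of nonnegative counts with positive margins.
#' @return List: `chi2`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop_degenerate_table("every row and column margin must be positive")
  n <- sum(table)
  expected <- outer(rs, cs) / n
  chi2 <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' One-way ANOVA with Bonferroni post-hoc t-tests
#'
#' Classical one-way F from group summaries (computable from printed
#' means/SDs/ns); pairwise pooled t-tests with p multiplied by the number
#' of comparisons, capped at 1.
#'
#' @param groups List of `group_summary` objects or raw numeric vectors,
#'   optionally named.
#' @return List: `F`, `df_between`, `df_within`, `p`, and `pairwise`
#'   (data.frame group_a, group_b, t, df, p_uncorrected, p_bonferroni).
#' @export
oneway_anova_bonferroni <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  gs <- lapply(groups, as_group_summary)
  nm <- names(gs) %||% paste0("group", seq_along(gs))
  if (is.null(names(gs)) || any(names(gs) == "")) names(gs) <- nm

  ns <- vapply(gs, `[[`, 0, "n")
  ms <- vapply(gs, `[[`, 0, "mean")
  sds <- vapply(gs, `[[`, 0, "sd")
  N <- sum(ns); k <- length(gs)
  grand <- sum(ns * ms) / N
  ss_between <- sum(ns * (ms - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df_between <- k - 1L
  df_within <- as.integer(N - k)
  ms_within <- ss_within / df_within
  F <- if (ms_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else (ss_between / df_between) / ms_within
  p <- stats::pf(F, df_between, df_within, lower.tail = FALSE)

  pairs <- utils::combn(seq_len(k), 2)
  n_cmp <- ncol(pairs)
  pairwise <- do.call(rbind, lapply(seq_len(n_cmp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- t_from_summary(gs[[i1]], gs[[i2]])
    data.frame(group_a = names(gs)[i1], group_b = names(gs)[i2],
               t = tt$t, df = tt$df, p_uncorrected = tt$p_two_tailed,
               p_bonferroni = min(1, tt$p_two_tailed * n_cmp))
  }))
  list(F = F, df_between = df_between, df_within = df_within, p = p,
       pairwise = pairwise)
}
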