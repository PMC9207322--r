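#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1
#' degrees of freedom (wraps [stats::kruskal.test()]).
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Mann-Whitney U test
#'
#' U counts the pairs in which the first sample exceeds the second
#' (R's `wilcox.test` convention, so `U(a, b) + U(b, a) = n_a * n_b`).
#' P-values come from exact enumeration when `n_a * n_b <= 400` and
#' there are no ties, otherwise from the tie-corrected normal
#' approximation (no continuity correction, so identical samples give
#' p = 1).
#'
#' @param a,b Numeric samples.
#' @return List with `U`, `p.value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  exact <- length(a) * length(b) <= 400 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p.value = wt$p.value,
       method = if (exact) "exact" else "normal_tie_corrected")
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` on an r x c count table,
#' `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param table Matrix of nonnegative integer counts with positive row
#'   and column sums.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(abs(table - round(table)) > 1e-8))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate input: zero row or column marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}

# one-step percentage-bend measure of location (Wilcox)
pb_location <- function(x, beta = 0.2, omega = NULL) {
  if (is.null(omega)) omega <- pb_scale(x, beta)
  psi <- (x - stats::median(x)) / omega
  i1 <- sum(psi < -1)
  i2 <- sum(psi > 1)
  sx <- ifelse(abs(psi) > 1, 0, x)
  (sum(sx) + omega * (i2 - i1)) / (length(x) - i1 - i2)
}

# percentage-bend measure of scale: the (1 - beta) empirical quantile of
# absolute deviations from the median
pb_scale <- function(x, beta = 0.2) {
  w <- sort(abs(x - stats::median(x)))
  w[max(1L, floor((1 - beta) * length(x)))]
}

#' Robust percentage-bend correlation
#'
#' Wilcox's percentage-bend correlation: deviations from a robust
#' location are scaled by the percentage-bend measure of scale, clipped
#' by the bending Psi-function at +/-1 (downweighting the `beta`
#' fraction of most outlying observations per variable), and
#' correlated. The test statistic uses the usual t approximation with
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @param beta Bending constant in (0, 0.5], default 0.2.
#' @return List with `r_pb`, `statistic`, `p.value`, `n`, and
#'   `undefined` (TRUE when a variable has zero robust scale).
#' @export
percentage_bend_correlation <- function(x, y, beta = 0.2) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stop("need at least 5 paired observations", call. = FALSE)
  if (beta <= 0 || beta > 0.5) stop("beta must be in (0, 0.5]", call. = FALSE)
  omx <- pb_scale(x, beta)
  omy <- pb_scale(y, beta)
  if (omx <= 0 || omy <= 0)
    return(list(r_pb = NA_real_, statistic = NA_real_, p.value = NA_real_,
                n = n, undefined = TRUE))
  a <- pmin(1, pmax(-1, (x - pb_location(x, beta, omx)) / omx))
  b <- pmin(1, pmax(-1, (y - pb_location(y, beta, omy)) / omy))
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tst <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r_pb = r, statistic = tst,
       p.value = 2 * stats::pt(-abs(tst), n - 2), n = n, undefined = FALSE)
}
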