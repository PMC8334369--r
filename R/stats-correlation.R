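# Rank-based correlation coefficients. Thresholding in the pipeline acts on
# rho/tau themselves; p-values, where offered, use large-sample
# approximations and are labelled as such.

average_ranks <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Pearson correlation of average-rank vectors; ties receive average ranks.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\]; NA if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_rho: unequal lengths")
  if (length(x) < 3L) stop("spearman_rho: need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("spearman_rho: missing values not allowed")
  rx <- average_ranks(x); ry <- average_ranks(y)
  sx <- sum((rx - mean(rx))^2); sy <- sum((ry - mean(ry))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sx * sy)
}

#' Kendall rank correlation (tau-b)
#'
#' Concordant/discordant pair statistic with tie normalization:
#' tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2)) where n0 = n(n-1)/2 and
#' n1, n2 are tie corrections for each margin. O(n^2) pair enumeration;
#' sample sizes in this pipeline are tens of placentas.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return tau in \[-1, 1\]; NA if either vector is constant.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("kendall_tau: unequal lengths")
  n <- length(x)
  if (n < 3L) stop("kendall_tau: need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("kendall_tau: missing values not allowed")
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) return(NA_real_)
  s / denom
}

#' Normal-approximation p-value for Kendall's tau
#'
#' Two-sided p from z = 3 tau sqrt(n(n-1)) / sqrt(2(2n+5)); the no-tie
#' variance is used, which is adequate for screening significant target
#' correlations at moderate n. Documented approximation.
#'
#' @param tau tau-b value.
#' @param n sample size.
#' @return two-sided p-value.
#' @export
kendall_tau_pvalue <- function(tau, n) {
  if (is.na(tau)) return(NA_real_)
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  2 * stats::pnorm(-abs(z))
}

#' t-approximation p-value for Spearman's rho
#'
#' Two-sided p from t = rho sqrt((n-2)/(1-rho^2)) on n-2 df. Documented
#' approximation; pipeline thresholds act on rho itself.
#'
#' @param rho rho value.
#' @param n sample size.
#' @return two-sided p-value.
#' @export
spearman_rho_pvalue <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}
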