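new_test_result <- function(statistic, df, p_value, method) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(
    list(statistic = statistic, df = df, p_value = p_value, method = method),
    class = "pmir_test"
  )
}

#' @export
print.pmir_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6),
      if (!is.null(x$df) && !is.na(x$df)) paste0("(df = ", x$df, ")") else "",
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: sorted p-values are multiplied by n/rank
#' and a running minimum is taken from the largest p downwards, capped at 1.
#' Adjusted values are never below the raw p-values and preserve their order.
#'
#' @param p_values numeric vector of raw p-values, all in \[0, 1\], no NA.
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p)) {
    stop("bh_adjust: missing p-value at index ",
         paste(which(is.na(p)), collapse = ", "))
  }
  bad <- which(p < 0 | p > 1)
  if (length(bad)) {
    stop("bh_adjust: p-value outside [0, 1] at index ",
         paste(bad, collapse = ", "))
  }
  n <- length(p)
  if (n <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * n / seq(n, 1L)))
  adj[order(o)]
}

#' Exact two-sided binomial test
#'
#' Two-sided p-value defined as 2 * min(lower tail, upper tail), capped at 1.
#' At `p0 = 0.5` this coincides with the usual sum of probabilities no larger
#' than the observed one, by symmetry of the null distribution.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param p0 null success probability, default 0.5.
#' @return a `pmir_test` with the number of successes as statistic.
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop("binomial_two_sided: k and n must be single non-missing counts")
  }
  if (n < 1) stop("binomial_two_sided: n must be >= 1")
  if (k < 0 || k > n) stop("binomial_two_sided: k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("binomial_two_sided: p0 must lie in (0, 1)")
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  new_test_result(statistic = k, df = NA_real_, p_value = p,
                  method = sprintf("exact two-sided binomial (n = %d, p0 = %g)", n, p0))
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic on an R x C contingency table with
#' df = (R - 1)(C - 1). The Yates continuity correction (2 x 2 only) is off
#' by default.
#'
#' @param table matrix of nonnegative counts; all row/column sums must be > 0.
#' @param yates apply the continuity correction (2 x 2 tables only).
#' @return a `pmir_test`.
#' @export
chi2_independence <- function(table, yates = FALSE) {
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0)) {
    stop("chi2_independence: table must be nonnegative with no missing values")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("chi2_independence: table must be at least 2 x 2")
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chi2_independence: zero row or column marginal")
  }
  expected <- outer(rs, cs) / sum(m)
  if (yates) {
    if (!all(dim(m) == c(2L, 2L))) {
      stop("chi2_independence: Yates correction is defined for 2 x 2 tables only")
    }
    stat <- sum((pmax(0, abs(m - expected) - 0.5))^2 / expected)
  } else {
    stat <- sum((m - expected)^2 / expected)
  }
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  new_test_result(stat, df, p,
                  method = if (yates) "Pearson chi-squared (Yates)" else "Pearson chi-squared")
}

#' Kruskal-Wallis rank test
#'
#' H statistic with average ranks over the pooled sample and the standard
#' tie correction, referred to a chi-squared distribution on (groups - 1)
#' degrees of freedom.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return a `pmir_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis: need a list of at least 2 groups")
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("kruskal_wallis: every group must be nonempty")
  }
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("kruskal_wallis: missing values not allowed")
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x, ties.method = "average")
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr <= 0) {
    # all observations identical: no evidence against the null
    return(new_test_result(0, length(groups) - 1L, 1, "Kruskal-Wallis"))
  }
  h <- h / tie_corr
  df <- length(groups) - 1L
  new_test_result(h, df, stats::pchisq(h, df, lower.tail = FALSE),
                  "Kruskal-Wallis")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of heterozygote-count configurations no more likely
#' than the observed one (hypergeometric-type enumeration).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return a `pmir_test`; the statistic is the observed heterozygote count.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("hwe_exact: genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("hwe_exact: total genotype count must be > 0")
  n_a <- 2 * n_aa + n_Aa           # rarer-allele count by convention
  n_A <- 2 * n_AA + n_Aa
  if (n_a > n_A) { tmp <- n_a; n_a <- n_A; n_A <- tmp }
  if (n_a == 0) {
    return(new_test_result(n_Aa, NA_real_, 1, "exact HWE"))
  }
  hets <- seq(n_a %% 2, n_a, by = 2)
  # log P(het = h | allele counts) up to a shared constant
  logp <- lgamma(n + 1) - lgamma((n_A - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_a - hets) / 2 + 1) + hets * log(2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_Aa)
  if (length(obs) != 1L) {
    stop("hwe_exact: observed heterozygote count inconsistent with allele counts")
  }
  p <- sum(prob[prob <= prob[obs] * (1 + 1e-12)])
  new_test_result(n_Aa, NA_real_, min(1, p), "exact HWE")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-study effect estimates with weights w_i = 1/se_i^2:
#' pooled beta = sum(w b)/sum(w), pooled se = 1/sqrt(sum(w)), two-sided
#' normal p on z = beta/se.
#'
#' @param betas numeric vector of study effect estimates.
#' @param ses positive standard errors, same length.
#' @return list with `pooled_beta`, `pooled_se`, `z`, `p_value`, `n_studies`,
#'   `study_weights` (normalized to sum to 1); class `pmir_meta`.
#' @export
fixed_effect_meta <- function(betas, ses) {
  if (length(betas) != length(ses) || length(betas) < 1L) {
    stop("fixed_effect_meta: betas and ses must be nonempty and equal length")
  }
  if (anyNA(betas) || anyNA(ses) || any(ses <= 0)) {
    stop("fixed_effect_meta: all SEs must be positive and inputs non-missing")
  }
  w <- 1 / ses^2
  pooled_beta <- sum(w * betas) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled_beta / pooled_se
  structure(
    list(pooled_beta = pooled_beta, pooled_se = pooled_se, z = z,
         p_value = 2 * stats::pnorm(-abs(z)), n_studies = length(betas),
         study_weights = w / sum(w)),
    class = "pmir_meta"
  )
}

#' @export
print.pmir_meta <- function(x, ...) {
  cat(sprintf("fixed-effect meta-analysis of %d studies\n", x$n_studies))
  cat(sprintf("  pooled beta = %.4g (SE %.4g), z = %.3f, p = %s\n",
              x$pooled_beta, x$pooled_se, x$z, format.pval(x$p_value, digits = 4)))
  invisible(x)
}
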