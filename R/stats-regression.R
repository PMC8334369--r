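# Regression machinery for the eQTL scan and trait association. Fits are
# plain least squares / IRLS with Wald tests, matching the additive-model
# association setting; no shrinkage, no robust options.

new_regression_fit <- function(coefficients, standard_errors, wald_stats,
                               p_values, residual_df, converged) {
  structure(
    list(coefficients = coefficients, standard_errors = standard_errors,
         wald_stats = wald_stats, p_values = p_values,
         residual_df = residual_df, converged = converged),
    class = "pmir_fit"
  )
}

#' @export
print.pmir_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    stat = x$wald_stats, p = x$p_values)
  print(tab, digits = 4)
  cat("residual df:", x$residual_df,
      if (!x$converged) " [NOT converged]" else "", "\n")
  invisible(x)
}

build_design <- function(X, n) {
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  cbind("(Intercept)" = rep(1, nrow(X)), X)
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  qr_x
}

#' Ordinary least-squares fit with Wald t-tests
#'
#' Adds an intercept, solves the normal equations via QR, and reports
#' per-coefficient standard errors from the residual variance with
#' two-sided t p-values on the residual degrees of freedom.
#'
#' @param y numeric response.
#' @param X predictor matrix (without intercept); may be NULL for an
#'   intercept-only fit.
#' @return a `pmir_fit`.
#' @export
linear_fit <- function(y, X = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("linear_fit: missing values in response")
  D <- build_design(X, length(y))
  if (nrow(D) != length(y)) stop("linear_fit: rows of X must match length of y")
  if (anyNA(D)) stop("linear_fit: missing values in predictors")
  qr_x <- check_full_rank(D)
  beta <- qr.coef(qr_x, y)
  resid <- y - drop(D %*% beta)
  df <- length(y) - ncol(D)
  if (df < 1) stop("linear_fit: no residual degrees of freedom")
  sigma2 <- sum(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(0, sigma2 * diag(xtx_inv)))
  stat <- ifelse(se > 0, beta / se, NA_real_)
  p <- 2 * stats::pt(-abs(stat), df = df)
  new_regression_fit(stats::setNames(beta, colnames(D)), se, stat, p,
                     residual_df = df, converged = TRUE)
}

#' Logistic regression via iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binomial GLM with logit link. Convergence is
#' declared when the log-likelihood changes by less than `tol` (default
#' 1e-8) within `max_iter` iterations. Complete or quasi-complete
#' separation manifests as diverging coefficients / degenerate fitted
#' probabilities and is reported through `converged = FALSE` rather than a
#' silently huge estimate.
#'
#' @param y binary response in \{0, 1\}; both classes must be present.
#' @param X predictor matrix (without intercept).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return a `pmir_fit` with Wald z p-values.
#' @export
logistic_fit <- function(y, X = NULL, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("logistic_fit: response must be binary 0/1 with no missing values")
  }
  if (length(unique(y)) < 2L) {
    stop("logistic_fit: both response classes must be present")
  }
  D <- build_design(X, length(y))
  if (nrow(D) != length(y)) stop("logistic_fit: rows of X must match length of y")
  if (anyNA(D)) stop("logistic_fit: missing values in predictors")
  check_full_rank(D)
  beta <- rep(0, ncol(D))
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(D, z, w)
    beta <- fit$coefficients
    eta <- drop(D %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  # separation heuristic: fitted probabilities pinned to 0/1 or exploding
  # linear predictor mean the MLE does not exist
  if (max(abs(drop(D %*% beta))) > 30 ||
      all(abs(mu - y) < 1e-8)) {
    converged <- FALSE
  }
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(D * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(cov)) {
    se <- rep(NA_real_, ncol(D)); converged <- FALSE
  } else {
    se <- sqrt(pmax(0, diag(cov)))
  }
  stat <- ifelse(!is.na(se) & se > 0, beta / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(stat))
  new_regression_fit(stats::setNames(beta, colnames(D)), se, stat, p,
                     residual_df = length(y) - ncol(D), converged = converged)
}
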