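# Negative-binomial Wald differential expression. This is a deliberately
# simplified stand-in for the full shrinkage machinery of mainstream count
# DE tools: per-feature method-of-moments dispersion with optional
# decile-median shrinkage, then a per-feature NB log-link GLM with size
# factors as offsets and a Wald test on the contrast coefficient. Its
# calls are validated by power/type-I simulation, not by matching any
# external tool feature-for-feature.

DISPERSION_FLOOR <- 1e-8

#' Method-of-moments dispersion estimates
#'
#' Per feature, within each group of >= 2 samples on normalized counts:
#' alpha_g = (s^2 - mean) / mean^2 (NB variance = mu + alpha mu^2), floored
#' at 1e-8 and averaged across groups. Optionally each estimate is shrunk
#' toward the median alpha of features in the same mean-expression decile.
#'
#' @param raw raw [count_matrix()].
#' @param groups character vector of group labels, one per sample (in
#'   column order of `raw`).
#' @param sf named size factors.
#' @param shrink weight in \[0, 1\] on the decile median (0 = none).
#' @return named numeric vector of dispersions alpha >= 1e-8.
#' @export
estimate_dispersion <- function(raw, groups, sf, shrink = 0.5) {
  stopifnot(inherits(raw, "count_matrix"), raw$kind == "raw")
  v <- sweep(raw$values, 2, sf[colnames(raw$values)], "/")
  groups <- as.character(groups)
  if (length(groups) != ncol(v)) {
    stop("estimate_dispersion: one group label per sample required")
  }
  use <- names(which(table(groups) >= 2))
  if (!length(use)) stop("estimate_dispersion: need >= 2 samples in some group")
  per_group <- sapply(use, function(g) {
    m <- v[, groups == g, drop = FALSE]
    mu <- rowMeans(m)
    s2 <- apply(m, 1, stats::var)
    ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
  })
  alpha <- pmax(DISPERSION_FLOOR, rowMeans(as.matrix(per_group), na.rm = TRUE))
  alpha[is.na(alpha)] <- DISPERSION_FLOOR
  if (shrink > 0) {
    base_mean <- rowMeans(v)
    dec <- cut(rank(base_mean, ties.method = "first"),
               breaks = 10, labels = FALSE)
    med <- tapply(alpha, dec, stats::median)
    alpha <- pmax(DISPERSION_FLOOR,
                  (1 - shrink) * alpha + shrink * med[dec])
  }
  stats::setNames(as.numeric(alpha), rownames(v))
}

# One NB log-link GLM fit with fixed dispersion and offsets.
# Returns beta vector, SEs, converged flag.
nb_glm_fit <- function(y, X, offset, alpha, tol = 1e-8, max_iter = 100L) {
  p <- ncol(X)
  beta <- numeric(p)
  # intercept start: log of offset-adjusted mean
  beta[1] <- log(max(mean(y / exp(offset)), 1e-8))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtwx <- crossprod(X * w, X)
    xtwz <- crossprod(X * w, z)
    new_beta <- tryCatch(drop(solve(xtwx, xtwz)), error = function(e) NULL)
    if (is.null(new_beta) || any(!is.finite(new_beta))) break
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  if (max(abs(beta)) > 20) converged <- FALSE   # boundary / all-zero group
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(crossprod(X * w, X)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(0, diag(cov)))
  list(beta = beta, se = se, converged = converged)
}

#' Negative-binomial Wald test between two groups
#'
#' Per-feature NB GLM of raw counts with log size factors as offsets and a
#' design of intercept + indicator(group == groupB) + optional fetal-sex
#' indicator. The Wald statistic on the contrast coefficient gets a
#' two-sided normal p; BH adjustment is applied across the features tested
#' in this contrast. `log2FC` is the contrast coefficient in base 2 and is
#' the change of `groupB` relative to `groupA`.
#'
#' @param raw raw [count_matrix()].
#' @param meta validated sample table covering the matrix samples.
#' @param contrast character pair `c(groupA, groupB)` of `group` labels.
#' @param covariates subset of `"fetal_sex"`.
#' @param sf named size factors.
#' @param disp named dispersions from [estimate_dispersion()].
#' @return data.frame (class `de_result`): feature_id, baseMean, log2FC,
#'   se_log2FC, wald_stat, p_value, fdr. Non-converged features carry NA
#'   p/fdr and are counted in `attr(, "n_nonconverged")`.
#' @export
nb_wald_test <- function(raw, meta, contrast, covariates = NULL, sf, disp) {
  stopifnot(inherits(raw, "count_matrix"), raw$kind == "raw",
            length(contrast) == 2L)
  if (!all(covariates %in% "fetal_sex")) {
    stop("nb_wald_test: supported covariates: fetal_sex")
  }
  meta <- validate_sample_table(meta)
  sel <- meta[meta$group %in% contrast, , drop = FALSE]
  n_by <- table(factor(sel$group, levels = contrast))
  if (any(n_by < 2)) {
    stop("nb_wald_test: both contrast groups need >= 2 samples; got ",
         paste(n_by, collapse = "/"))
  }
  missing_s <- setdiff(sel$sample_id, colnames(raw$values))
  if (length(missing_s)) {
    stop("nb_wald_test: sample(s) absent from count matrix: ",
         paste(utils::head(missing_s, 5), collapse = ", "))
  }
  v <- raw$values[, sel$sample_id, drop = FALSE]
  X <- cbind("(Intercept)" = 1,
             contrast = as.numeric(sel$group == contrast[2]))
  if ("fetal_sex" %in% covariates) {
    X <- cbind(X, fetal_sexXY = as.numeric(sel$fetal_sex == "XY"))
  }
  offset <- log(sf[sel$sample_id])
  feats <- rownames(v)
  miss_d <- setdiff(feats, names(disp))
  if (length(miss_d)) {
    stop("nb_wald_test: no dispersion for feature(s): ",
         paste(utils::head(miss_d, 5), collapse = ", "))
  }
  norm <- sweep(v, 2, exp(offset), "/")
  out <- data.frame(
    feature_id = feats, baseMean = rowMeans(norm),
    log2FC = NA_real_, se_log2FC = NA_real_, wald_stat = NA_real_,
    p_value = NA_real_, fdr = NA_real_, stringsAsFactors = FALSE
  )
  n_bad <- 0L
  for (i in seq_along(feats)) {
    fit <- nb_glm_fit(v[i, ], X, offset, disp[[feats[i]]])
    if (!fit$converged || is.na(fit$se[2]) || fit$se[2] <= 0) {
      n_bad <- n_bad + 1L
      next
    }
    z <- fit$beta[2] / fit$se[2]
    out$log2FC[i] <- fit$beta[2] / log(2)
    out$se_log2FC[i] <- fit$se[2] / log(2)
    out$wald_stat[i] <- z
    out$p_value[i] <- 2 * stats::pnorm(-abs(z))
  }
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_adjust(out$p_value[ok])
  rownames(out) <- NULL
  attr(out, "n_nonconverged") <- n_bad
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Classify differential-expression direction
#'
#' Up if fdr < alpha and log2FC > 0; Down if fdr < alpha and log2FC < 0;
#' NoChange otherwise (including NA fdr from non-converged fits).
#'
#' @param de a `de_result` (or any data.frame with fdr and log2FC).
#' @param alpha FDR threshold, default 0.05.
#' @return character vector named by feature id, values Up/Down/NoChange.
#' @export
classify_direction <- function(de, alpha = 0.05) {
  dir <- rep("NoChange", nrow(de))
  sig <- !is.na(de$fdr) & de$fdr < alpha
  dir[sig & de$log2FC > 0] <- "Up"
  dir[sig & de$log2FC < 0] <- "Down"
  stats::setNames(dir, de$feature_id)
}
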