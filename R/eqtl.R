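# Windowed cis miR-eQTL scan: SNV-miRNA pair enumeration within a +/-100 kb
# flank, MAF filtering with HWE reporting, per-pair additive linear
# regression of normalized expression on minor-allele dosage with fetal sex
# and gestational age as covariates, one BH correction over the whole scan,
# plus SNV -> pregnancy-trait association and fixed-effect meta-analysis.

#' Enumerate cis SNV-miRNA pairs
#'
#' A pair is included iff the SNV lies on the same chromosome and its
#' 0-based position falls in \[gene_start - flank, gene_end + flank): the
#' left edge is inclusive, the right edge exclusive, consistent with the
#' internal half-open convention.
#'
#' @param geno a `genotype_matrix`.
#' @param mirnas feature annotation data.frame (0-based half-open).
#' @param flank window size in bp on each side (default 100,000).
#' @return data.frame: snv_id, mirna_id.
#' @export
enumerate_pairs <- function(geno, mirnas, flank = 1e5) {
  stopifnot(inherits(geno, "genotype_matrix"), flank >= 0)
  snv <- geno$info
  out <- lapply(seq_len(nrow(mirnas)), function(i) {
    hit <- snv$chrom == mirnas$chrom[i] &
      snv$pos >= mirnas$start[i] - flank &
      snv$pos < mirnas$end[i] + flank
    if (!any(hit)) return(NULL)
    data.frame(snv_id = snv$snv_id[hit], mirna_id = mirnas$feature_id[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(snv_id = character(), mirna_id = character())
  }
  rownames(out) <- NULL
  out
}

#' MAF filter with HWE reporting
#'
#' Minor-allele frequency is computed on non-missing dosages; SNVs with
#' MAF strictly greater than `maf_min` are retained. The exact HWE p-value
#' is reported for every retained SNV; by default HWE is informational
#' only (`hwe_alpha = NULL`), since the upstream protocol tests HWE but
#' states no exclusion threshold.
#'
#' @param geno a `genotype_matrix` (minor-allele dosages).
#' @param maf_min MAF threshold (strict >), default 0.1.
#' @param hwe_alpha optional HWE p-value below which SNVs are ALSO dropped.
#' @return list: `genotypes` (filtered `genotype_matrix`), `report`
#'   (data.frame: snv_id, maf, hwe_p, kept).
#' @export
maf_hwe_filter <- function(geno, maf_min = 0.1, hwe_alpha = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  maf <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    f <- mean(x) / 2
    min(f, 1 - f)
  })
  hwe_p <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact(sum(x == 0), sum(x == 1), sum(x == 2))$p_value
  })
  kept <- !is.na(maf) & maf > maf_min
  if (!is.null(hwe_alpha)) kept <- kept & !is.na(hwe_p) & hwe_p >= hwe_alpha
  report <- data.frame(snv_id = geno$info$snv_id, maf = maf, hwe_p = hwe_p,
                       kept = kept, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(
    genotypes = new_genotypes(d[kept, , drop = FALSE],
                              geno$info[kept, , drop = FALSE]),
    report = report
  )
}

covariate_design <- function(meta, covariates) {
  X <- NULL
  if ("fetal_sex" %in% covariates) {
    X <- cbind(X, fetal_sexXY = as.numeric(meta$fetal_sex == "XY"))
  }
  if ("gestational_days" %in% covariates) {
    X <- cbind(X, gestational_days = as.numeric(meta$gestational_days))
  }
  X
}

#' Windowed cis miR-eQTL scan
#'
#' For each enumerated pair, linear regression of normalized miRNA
#' expression on minor-allele dosage plus covariates over complete cases.
#' Pairs with fewer than `min_n` complete cases, or a constant dosage after
#' case removal, are skipped and logged. One BH correction over all tests
#' in the scan; results sorted by fdr.
#'
#' @param expr normalized [count_matrix()] of miRNA expression.
#' @param geno a `genotype_matrix` (after [maf_hwe_filter()]).
#' @param meta validated sample table.
#' @param pairs data.frame from [enumerate_pairs()].
#' @param covariates subset of c("fetal_sex", "gestational_days").
#' @param min_n minimum complete cases per test (default 10).
#' @return data.frame: snv_id, mirna_id, n_used, beta, se, p_value, fdr,
#'   maf, hwe_p; `attr(, "skipped")` records skipped pairs with reasons.
#' @export
eqtl_scan <- function(expr, geno, meta, pairs,
                      covariates = c("fetal_sex", "gestational_days"),
                      min_n = 10L) {
  stopifnot(inherits(expr, "count_matrix"), inherits(geno, "genotype_matrix"))
  if (!all(covariates %in% c("fetal_sex", "gestational_days"))) {
    stop("eqtl_scan: supported covariates: fetal_sex, gestational_days")
  }
  meta <- validate_sample_table(meta)
  samples <- Reduce(intersect, list(colnames(expr$values),
                                    colnames(geno$dosages), meta$sample_id))
  if (length(samples) < min_n) {
    stop("eqtl_scan: fewer than ", min_n, " samples shared by expression, ",
         "genotypes and metadata")
  }
  miss_m <- setdiff(pairs$mirna_id, rownames(expr$values))
  if (length(miss_m)) {
    stop("eqtl_scan: expression missing for miRNA(s): ",
         paste(utils::head(miss_m, 5), collapse = ", "))
  }
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  covX <- covariate_design(meta, covariates)
  snv_stats <- maf_hwe_filter(geno, maf_min = -1)$report  # maf/hwe lookup only
  rows <- vector("list", nrow(pairs))
  skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$snv_id[i]; mid <- pairs$mirna_id[i]
    if (!sid %in% rownames(geno$dosages)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(snv_id = sid, mirna_id = mid, reason = "snv_filtered")
      next
    }
    dose <- geno$dosages[sid, samples]
    ok <- !is.na(dose)
    if (sum(ok) < min_n) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(snv_id = sid, mirna_id = mid, reason = "too_few_complete_cases")
      next
    }
    if (length(unique(dose[ok])) < 2L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(snv_id = sid, mirna_id = mid, reason = "constant_dosage")
      next
    }
    y <- expr$values[mid, samples][ok]
    X <- cbind(dosage = dose[ok],
               if (!is.null(covX)) covX[ok, , drop = FALSE])
    fit <- linear_fit(y, X)
    rows[[i]] <- data.frame(
      snv_id = sid, mirna_id = mid, n_used = sum(ok),
      beta = fit$coefficients[["dosage"]],
      se = fit$standard_errors[[which(names(fit$coefficients) == "dosage")]],
      p_value = fit$p_values[[which(names(fit$coefficients) == "dosage")]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snv_id = character(), mirna_id = character(),
                      n_used = integer(), beta = numeric(), se = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      maf = numeric(), hwe_p = numeric())
  } else {
    out$fdr <- bh_adjust(out$p_value)
    idx <- match(out$snv_id, snv_stats$snv_id)
    out$maf <- snv_stats$maf[idx]
    out$hwe_p <- snv_stats$hwe_p[idx]
    out <- out[order(out$fdr, out$snv_id, out$mirna_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' SNV to pregnancy-trait association
#'
#' Additive-model regression of each trait on minor-allele dosage plus
#' covariates: linear for continuous traits, logistic for binary (0/1)
#' traits. BH correction across all trait x SNV tests run together.
#'
#' @param meta validated sample table carrying the trait columns.
#' @param geno a `genotype_matrix`.
#' @param traits character vector of trait column names in `meta`.
#' @param covariates subset of c("fetal_sex", "gestational_days").
#' @param min_n minimum complete cases per test.
#' @return data.frame: snv_id, trait, model, beta, se, p_value, fdr, n_used.
#' @export
trait_association <- function(meta, geno, traits,
                              covariates = c("fetal_sex", "gestational_days"),
                              min_n = 10L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  meta <- validate_sample_table(meta)
  miss <- setdiff(traits, names(meta))
  if (length(miss)) {
    stop("trait_association: unknown trait column(s): ",
         paste(miss, collapse = ", "))
  }
  samples <- intersect(meta$sample_id, colnames(geno$dosages))
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  covX <- covariate_design(meta, covariates)
  rows <- list()
  for (tr in traits) {
    y_all <- meta[[tr]]
    is_binary <- all(stats::na.omit(y_all) %in% c(0, 1))
    for (sid in rownames(geno$dosages)) {
      dose <- geno$dosages[sid, samples]
      ok <- !is.na(dose) & !is.na(y_all)
      if (sum(ok) < min_n) next
      if (length(unique(dose[ok])) < 2L) next
      X <- cbind(dosage = dose[ok],
                 if (!is.null(covX)) covX[ok, , drop = FALSE])
      y <- y_all[ok]
      if (is_binary) {
        if (length(unique(y)) < 2L) {
          stop("trait_association: trait '", tr,
               "' has a single class among complete cases")
        }
        fit <- logistic_fit(y, X)
        model <- "logistic"
        if (!fit$converged) next
      } else {
        fit <- linear_fit(y, X)
        model <- "linear"
      }
      j <- which(names(fit$coefficients) == "dosage")
      rows[[length(rows) + 1L]] <- data.frame(
        snv_id = sid, trait = tr, model = model,
        beta = fit$coefficients[[j]], se = fit$standard_errors[[j]],
        p_value = fit$p_values[[j]], n_used = sum(ok),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(snv_id = character(), trait = character(),
                      model = character(), beta = numeric(), se = numeric(),
                      p_value = numeric(), fdr = numeric(), n_used = integer()))
  }
  out$fdr <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Fixed-effect meta-analysis across cohorts
#'
#' Pools per-cohort association results (inverse-variance fixed effect)
#' for every SNV-trait pair present in at least `min_cohorts` cohorts,
#' then BH-adjusts across pooled pairs.
#'
#' @param cohort_results named list of data.frames with columns snv_id,
#'   trait, beta, se (e.g. outputs of [trait_association()]).
#' @param min_cohorts minimum cohorts per pair (default: all).
#' @return data.frame: snv_id, trait, n_studies, pooled_beta, pooled_se,
#'   z, p_value, fdr.
#' @export
meta_across_cohorts <- function(cohort_results,
                                min_cohorts = length(cohort_results)) {
  stopifnot(is.list(cohort_results), length(cohort_results) >= 1L)
  all_res <- do.call(rbind, lapply(seq_along(cohort_results), function(i) {
    r <- cohort_results[[i]]
    stopifnot(all(c("snv_id", "trait", "beta", "se") %in% names(r)))
    cbind(r[, c("snv_id", "trait", "beta", "se")], cohort = i)
  }))
  key <- paste(all_res$snv_id, all_res$trait, sep = "\r")
  rows <- lapply(split(all_res, key), function(d) {
    if (nrow(d) < min_cohorts) return(NULL)
    m <- fixed_effect_meta(d$beta, d$se)
    data.frame(snv_id = d$snv_id[1], trait = d$trait[1],
               n_studies = m$n_studies, pooled_beta = m$pooled_beta,
               pooled_se = m$pooled_se, z = m$z, p_value = m$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(snv_id = character(), trait = character(),
                      n_studies = integer(), pooled_beta = numeric(),
                      pooled_se = numeric(), z = numeric(),
                      p_value = numeric(), fdr = numeric()))
  }
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$fdr, out$snv_id, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out
}
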