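# Entry criteria of the analysis: miRNAs must show a median raw read count
# strictly over the threshold across ALL samples before any testing, and
# libraries are normalized by median-of-ratios size factors.

#' Median-count expression filter
#'
#' Keeps features whose median raw count across all samples is strictly
#' greater than `threshold` (default 50). The strictness matches the
#' "over 50" entry criterion: a feature at exactly 50 in every sample is
#' dropped.
#'
#' @param raw a raw [count_matrix()].
#' @param threshold count threshold (strict >).
#' @return list: `counts` (filtered matrix), `kept`, `dropped` (feature ids).
#' @export
filter_by_median <- function(raw, threshold = 50) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$kind != "raw") {
    stop("filter_by_median: input must be raw counts, got '", raw$kind, "'")
  }
  med <- apply(raw$values, 1, stats::median)
  keep <- med > threshold
  list(
    counts = count_matrix(raw$values[keep, , drop = FALSE], "raw"),
    kept = rownames(raw$values)[keep],
    dropped = rownames(raw$values)[!keep]
  )
}

#' Median-of-ratios size factors
#'
#' Per-feature reference = geometric mean of its counts over samples,
#' restricted to features positive in every sample; the size factor of a
#' sample is the median over those features of count / reference.
#'
#' @param raw a raw [count_matrix()].
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(raw) {
  stopifnot(inherits(raw, "count_matrix"))
  v <- raw$values
  all_pos <- rowSums(v <= 0) == 0
  if (!any(all_pos)) {
    stop("size_factors: no feature has positive counts in every sample; ",
         "filter to well-expressed features first")
  }
  lv <- log(v[all_pos, , drop = FALSE])
  ref <- rowMeans(lv)                       # log geometric mean
  sf <- apply(lv - ref, 2, function(z) exp(stats::median(z)))
  gm <- exp(mean(log(sf)))
  if (gm < 0.5 || gm > 2) {
    warning("size_factors: geometric mean of factors is ", signif(gm, 3),
            "; libraries look unbalanced")
  }
  sf
}

#' Apply size factors
#'
#' Divides each sample column by its size factor.
#'
#' @param raw a raw [count_matrix()].
#' @param sf named size factors covering all samples.
#' @return a normalized [count_matrix()].
#' @export
normalize_counts <- function(raw, sf) {
  stopifnot(inherits(raw, "count_matrix"))
  miss <- setdiff(colnames(raw$values), names(sf))
  if (length(miss)) {
    stop("normalize_counts: no size factor for sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  if (any(sf <= 0)) stop("normalize_counts: size factors must be positive")
  v <- sweep(raw$values, 2, sf[colnames(raw$values)], "/")
  count_matrix(v, "normalized")
}

#' Counts per million
#'
#' value * 1e6 / column sum, computed on the library sizes of the matrix
#' given (i.e. post-filter totals when called on a filtered matrix; pass
#' `lib_sizes` to use pre-filter totals instead).
#'
#' @param raw a raw [count_matrix()].
#' @param lib_sizes optional named per-sample library sizes overriding the
#'   column sums.
#' @return a cpm [count_matrix()].
#' @export
cpm <- function(raw, lib_sizes = NULL) {
  stopifnot(inherits(raw, "count_matrix"))
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(raw$values)
  } else {
    miss <- setdiff(colnames(raw$values), names(lib_sizes))
    if (length(miss)) {
      stop("cpm: no library size for sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    lib_sizes <- lib_sizes[colnames(raw$values)]
  }
  if (any(lib_sizes <= 0)) stop("cpm: nonpositive library size")
  count_matrix(sweep(raw$values, 2, lib_sizes, "/") * 1e6, "cpm")
}
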