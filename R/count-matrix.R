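#' Expression count matrix
#'
#' Feature x sample grid with aligned unique identifiers. `kind` tracks the
#' measurement scale: `"raw"` (nonnegative integers), `"normalized"`
#' (size-factor scaled) or `"cpm"` (counts per million).
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param kind one of "raw", "normalized", "cpm".
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(values, kind = c("raw", "normalized", "cpm")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("count_matrix: values must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("count_matrix: duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    stop("count_matrix: duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1])
  }
  if (anyNA(values)) stop("count_matrix: missing values not allowed")
  if (any(values < 0)) stop("count_matrix: negative values not allowed")
  if (kind == "raw" && any(values != round(values))) {
    bad <- which(values != round(values), arr.ind = TRUE)[1, ]
    stop("count_matrix: raw counts must be integers; feature '",
         rownames(values)[bad[1]], "', sample '", colnames(values)[bad[2]], "'")
  }
  structure(list(values = values, kind = kind), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

feature_ids <- function(cm) rownames(cm$values)
sample_ids <- function(cm) colnames(cm$values)

#' Subset a count matrix
#'
#' @param cm a `count_matrix`.
#' @param features,samples character vectors of ids to keep (NULL = all).
#' @return a `count_matrix` of the same kind.
#' @export
subset_counts <- function(cm, features = NULL, samples = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- cm$values
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(v))
    if (length(missing_f)) {
      stop("subset_counts: unknown feature id(s): ",
           paste(utils::head(missing_f, 5), collapse = ", "))
    }
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(v))
    if (length(missing_s)) {
      stop("subset_counts: unknown sample id(s): ",
           paste(utils::head(missing_s, 5), collapse = ", "))
    }
    v <- v[, samples, drop = FALSE]
  }
  count_matrix(v, cm$kind)
}
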