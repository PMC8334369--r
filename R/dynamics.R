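# Nine-pattern taxonomy of gestational expression dynamics: each miRNA is
# labelled by the ordered pair of Up/Down/NoChange calls for the first ->
# second trimester and second trimester -> term transitions, and pattern
# composition is cross-tabulated against the genomic cluster categories.

PATTERN_LEVELS <- as.vector(outer(c("Down", "Up", "NoChange"),
                                  c("Down", "Up", "NoChange"),
                                  function(a, b) paste(a, b, sep = "-")))

#' Assign gestational dynamics patterns
#'
#' Combines the per-comparison direction calls of the two trimester
#' transitions into one of nine ordered-pair patterns.
#'
#' @param de_t1_t2 `de_result` for the first -> second trimester contrast.
#' @param de_t2_term `de_result` for the second trimester -> term contrast.
#' @param alpha FDR threshold for each call.
#' @return data.frame: feature_id, first_transition, second_transition,
#'   pattern ("<first>-<second>").
#' @export
assign_pattern <- function(de_t1_t2, de_t2_term, alpha = 0.05) {
  only1 <- setdiff(de_t1_t2$feature_id, de_t2_term$feature_id)
  only2 <- setdiff(de_t2_term$feature_id, de_t1_t2$feature_id)
  if (length(only1) || length(only2)) {
    stop("assign_pattern: feature sets differ between the two tables: ",
         paste(utils::head(c(only1, only2), 5), collapse = ", "))
  }
  d1 <- classify_direction(de_t1_t2, alpha)
  d2 <- classify_direction(de_t2_term, alpha)[names(d1)]
  data.frame(
    feature_id = names(d1),
    first_transition = unname(d1),
    second_transition = unname(d2),
    pattern = factor(paste(d1, d2, sep = "-"), levels = PATTERN_LEVELS),
    stringsAsFactors = FALSE
  )
}

#' Cross-tabulate patterns by genomic cluster
#'
#' One column per cluster category (All, C19MC, C14MC, miR371_373, other),
#' one row per pattern, with column percentages alongside the counts.
#'
#' @param patterns data.frame from [assign_pattern()].
#' @param annotation feature annotation carrying the `cluster` column.
#' @return list: `counts` (9 x 5 matrix), `percent` (same shape; columns
#'   sum to 100 for nonempty categories).
#' @export
summarize_patterns <- function(patterns, annotation) {
  cl <- annotation$cluster[match(patterns$feature_id, annotation$feature_id)]
  if (anyNA(cl)) {
    stop("summarize_patterns: unannotated feature(s): ",
         paste(utils::head(patterns$feature_id[is.na(cl)], 5), collapse = ", "))
  }
  cl <- factor(cl, levels = CLUSTER_LEVELS)
  pat <- factor(patterns$pattern, levels = PATTERN_LEVELS)
  by_cluster <- table(pat, cl)
  counts <- cbind(All = table(pat), by_cluster)
  totals <- colSums(counts)
  percent <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  percent[, totals == 0] <- 0
  list(counts = unclass(counts), percent = unclass(percent))
}

#' Chi-squared comparison of target-gene counts
#'
#' 2 x 2 independence test of the numbers of target genes of up- vs
#' downregulated miRNAs in two transitions.
#'
#' @param n_up_targets,n_down_targets counts for the first transition.
#' @param n_up_targets2,n_down_targets2 counts for the second transition.
#' @return a `pmir_test` (no continuity correction).
#' @export
compare_target_counts <- function(n_up_targets, n_down_targets,
                                  n_up_targets2, n_down_targets2) {
  chi2_independence(matrix(c(n_up_targets, n_down_targets,
                             n_up_targets2, n_down_targets2),
                           nrow = 2, byrow = TRUE))
}
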