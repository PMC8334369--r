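# miRNA x transcriptome correlation landscape: the full Spearman rho grid
# over a shared sample set, hierarchical grouping of miRNAs by their
# correlation profiles, thresholded per-group correlated-gene lists, a
# sign-balance test among predicted targets, and hypergeometric
# over-representation against a custom background.

#' Pairwise miRNA-gene Spearman correlation matrix
#'
#' Rank-transforms each expression row over the shared samples and takes
#' the Pearson cross-correlation of the rank matrices, which equals the
#' per-pair Spearman rho with average ranks.
#'
#' @param mirna_expr [count_matrix()] of miRNA expression.
#' @param gene_expr [count_matrix()] of gene expression.
#' @return list (class `correlation_matrix`): `rho` (miRNA x gene matrix),
#'   `n_samples`, `samples`.
#' @export
pairwise_spearman <- function(mirna_expr, gene_expr) {
  stopifnot(inherits(mirna_expr, "count_matrix"),
            inherits(gene_expr, "count_matrix"))
  shared <- intersect(colnames(mirna_expr$values), colnames(gene_expr$values))
  if (length(shared) < 3L) {
    stop("pairwise_spearman: need >= 3 shared samples, got ", length(shared))
  }
  rank_rows <- function(m) t(apply(m[, shared, drop = FALSE], 1, average_ranks))
  rm_ <- rank_rows(mirna_expr$values)
  rg <- rank_rows(gene_expr$values)
  rho <- suppressWarnings(stats::cor(t(rm_), t(rg)))  # constant rows -> NA
  structure(
    list(rho = rho, n_samples = length(shared), samples = shared),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d miRNAs x %d genes over %d samples (%d pairs)\n",
              nrow(x$rho), ncol(x$rho), x$n_samples, length(x$rho)))
  invisible(x)
}

#' Group miRNAs by their correlation profiles
#'
#' Agglomerative clustering of the miRNA rows of the rho matrix (Euclidean
#' distance, complete linkage by default), cut into `k` groups. Group
#' labels G1..Gk follow dendrogram leaf order; input rows are sorted
#' lexicographically first so ties break deterministically.
#'
#' @param corr a `correlation_matrix`.
#' @param k number of groups (default 5).
#' @param method linkage passed to [stats::hclust()].
#' @return list: `groups` (named character vector miRNA -> "G1".."Gk"),
#'   `k`, `tree` (the hclust object).
#' @export
cluster_mirnas <- function(corr, k = 5, method = "complete") {
  stopifnot(inherits(corr, "correlation_matrix"))
  m <- corr$rho[order(rownames(corr$rho)), , drop = FALSE]
  if (k > nrow(m)) stop("cluster_mirnas: k exceeds the number of miRNAs")
  if (anyNA(m)) stop("cluster_mirnas: rho matrix contains NA rows (constant profiles)")
  tree <- stats::hclust(stats::dist(m, method = "euclidean"), method = method)
  cut <- stats::cutree(tree, k = k)
  # relabel in dendrogram leaf order: first group encountered = G1
  leaf_order <- tree$labels[tree$order]
  first_seen <- unique(cut[leaf_order])
  relabel <- stats::setNames(paste0("G", seq_len(k)), first_seen)
  groups <- stats::setNames(unname(relabel[as.character(cut)]), names(cut))
  list(groups = groups, k = k, tree = tree)
}

#' Export a miRNA dendrogram in Newick format
#' @param clustering result of [cluster_mirnas()].
#' @param path output path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Thresholded correlated-gene lists for a miRNA group
#'
#' Negative list: genes whose median rho over the group's miRNAs is below
#' `-median_threshold` AND whose rho with EVERY miRNA in the group is below
#' `-individual_threshold`. The positive list mirrors this with > +0.3 /
#' > +0.1. The per-miRNA consistency bound makes the lists shrink (or stay)
#' as the group grows.
#'
#' @param corr a `correlation_matrix`.
#' @param group character vector of miRNA ids (rows of rho).
#' @param direction "negative" or "positive".
#' @param median_threshold,individual_threshold positive thresholds with
#'   0 < individual < median <= 1.
#' @return character vector of gene ids.
#' @export
correlated_gene_lists <- function(corr, group,
                                  direction = c("negative", "positive"),
                                  median_threshold = 0.3,
                                  individual_threshold = 0.1) {
  direction <- match.arg(direction)
  stopifnot(inherits(corr, "correlation_matrix"))
  if (!(individual_threshold > 0 && individual_threshold < median_threshold &&
        median_threshold <= 1)) {
    stop("correlated_gene_lists: need 0 < individual < median <= 1")
  }
  miss <- setdiff(group, rownames(corr$rho))
  if (!length(group)) stop("correlated_gene_lists: empty miRNA group")
  if (length(miss)) {
    stop("correlated_gene_lists: unknown miRNA(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  sub <- corr$rho[group, , drop = FALSE]
  med <- apply(sub, 2, stats::median)
  if (direction == "negative") {
    keep <- med < -median_threshold &
      colSums(sub < -individual_threshold) == length(group)
  } else {
    keep <- med > median_threshold &
      colSums(sub > individual_threshold) == length(group)
  }
  keep[is.na(keep)] <- FALSE
  colnames(corr$rho)[keep]
}

#' Sign balance of significant target correlations
#'
#' For one miRNA, computes the Kendall tau of its expression with each
#' expressed predicted target over the shared samples, keeps targets whose
#' tau is significant at `alpha` (normal approximation), counts negative vs
#' positive significant correlations, and tests the balance with the exact
#' two-sided binomial against 0.5.
#'
#' @param mirna_id miRNA identifier.
#' @param target_map data.frame from [read_target_map()].
#' @param mirna_expr,gene_expr [count_matrix()] objects sharing samples.
#' @param alpha per-target significance level.
#' @return list: `n_negative`, `n_positive`, `test` (`pmir_test`), `taus`
#'   (named tau of each expressed target).
#' @export
target_sign_balance <- function(mirna_id, target_map, mirna_expr, gene_expr,
                                alpha = 0.05) {
  stopifnot(mirna_id %in% rownames(mirna_expr$values))
  tg <- intersect(targets_of(target_map, mirna_id),
                  rownames(gene_expr$values))
  if (!length(tg)) {
    stop("target_sign_balance: no expressed targets for ", mirna_id)
  }
  shared <- intersect(colnames(mirna_expr$values), colnames(gene_expr$values))
  if (length(shared) < 3L) stop("target_sign_balance: < 3 shared samples")
  x <- mirna_expr$values[mirna_id, shared]
  taus <- vapply(tg, function(g) kendall_tau(x, gene_expr$values[g, shared]), 0)
  ps <- vapply(taus, kendall_tau_pvalue, 0, n = length(shared))
  sig <- !is.na(ps) & ps < alpha
  n_neg <- sum(sig & taus < 0)
  n_pos <- sum(sig & taus > 0)
  total <- n_neg + n_pos
  test <- if (total > 0) {
    binomial_two_sided(min(n_neg, n_pos), total)
  } else {
    new_test_result(0, NA_real_, 1, "exact two-sided binomial (no significant targets)")
  }
  list(n_negative = n_neg, n_positive = n_pos, test = test, taus = taus)
}

#' Hypergeometric over-representation against a custom background
#'
#' One-sided hypergeometric p per gene set: the probability of observing at
#' least the attained overlap between the query and the set, with the
#' universe restricted to the supplied background (sets are intersected
#' with the background before testing). BH adjustment across tested sets.
#'
#' @param query character vector of genes; must be a subset of `background`.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param background character vector defining the universe.
#' @return data.frame: set_id, set_size, query_hits, query_size,
#'   background_size, p_value, fdr.
#' @export
hypergeometric_enrichment <- function(query, sets, background) {
  query <- unique(query); background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray)) {
    stop("hypergeometric_enrichment: query gene(s) absent from background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  N <- length(background); n <- length(query)
  rows <- lapply(names(sets), function(id) {
    s <- intersect(sets[[id]], background)
    K <- length(s)
    if (K == 0L) return(NULL)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, set_size = K, query_hits = k, query_size = n,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_id = character(), set_size = integer(),
                      query_hits = integer(), query_size = integer(),
                      background_size = integer(), p_value = numeric(),
                      fdr = numeric()))
  }
  out$fdr <- bh_adjust(out$p_value)
  out
}
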