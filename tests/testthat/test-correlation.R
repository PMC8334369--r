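test_that("pairwise_spearman equals the per-pair loop and counts pairs", {
  set.seed(121)
  mir <- toy_counts(matrix(rpois(5 * 10, 100), nrow = 5), "normalized",
                    features = paste0("mir", 1:5))
  gene <- toy_counts(matrix(rpois(7 * 10, 200), nrow = 7), "normalized",
                     features = paste0("g", 1:7))
  corr <- pairwise_spearman(mir, gene)
  expect_equal(length(corr$rho), 5 * 7)
  for (i in 1:5) for (j in 1:7) {
    expect_equal(corr$rho[i, j],
                 spearman_rho(mir$values[i, ], gene$values[j, ]),
                 tolerance = 1e-12)
  }
  # a gene identical to a miRNA profile: rho 1
  gene2 <- toy_counts(rbind(gene$values, mirror = mir$values[1, ]),
                      "normalized",
                      features = c(paste0("g", 1:7), "mirror"))
  corr2 <- pairwise_spearman(mir, gene2)
  expect_equal(corr2$rho["mir1", "mirror"], 1)
  # monotone transform of an expression row leaves rho unchanged
  gene3 <- gene
  gene3$values[2, ] <- exp(gene3$values[2, ] / 100)
  expect_equal(pairwise_spearman(mir, gene3)$rho[, 2], corr$rho[, 2],
               tolerance = 1e-12)
  # fewer than 3 shared samples rejected
  mir_s <- subset_counts(mir, samples = c("s1", "s2"))
  expect_error(pairwise_spearman(mir_s, gene), "3 shared")
})

make_block_corr <- function() {
  # two miRNA blocks with opposite correlation profiles to disjoint genes
  set.seed(122)
  n <- 30
  latentA <- rnorm(n); latentB <- rnorm(n)
  mir <- rbind(
    t(replicate(4, latentA + rnorm(n, sd = 0.3))),
    t(replicate(4, latentB + rnorm(n, sd = 0.3)))
  )
  gene <- rbind(
    t(replicate(10, latentA + rnorm(n, sd = 0.5))),
    t(replicate(10, -latentB + rnorm(n, sd = 0.5)))
  )
  mir <- mir - min(mir) + 1; gene <- gene - min(gene) + 1
  list(
    mir = toy_counts(mir, "normalized", features = sprintf("mir%02d", 1:8)),
    gene = toy_counts(gene, "normalized", features = sprintf("g%02d", 1:20))
  )
}

test_that("cluster_mirnas recovers separable blocks deterministically", {
  b <- make_block_corr()
  corr <- pairwise_spearman(b$mir, b$gene)
  cl <- cluster_mirnas(corr, k = 2)
  g1 <- cl$groups[sprintf("mir%02d", 1:4)]
  g2 <- cl$groups[sprintf("mir%02d", 5:8)]
  expect_length(unique(g1), 1)
  expect_length(unique(g2), 1)
  expect_false(unique(g1) == unique(g2))
  # leaf-order labelling starts at G1
  expect_setequal(unique(cl$groups), c("G1", "G2"))
  # k = number of miRNAs: singletons
  cl_all <- cluster_mirnas(corr, k = 8)
  expect_equal(length(unique(cl_all$groups)), 8)
  # permutation invariance up to relabeling
  corr_perm <- corr
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  corr_perm$rho <- corr$rho[perm, ]
  cl_p <- cluster_mirnas(corr_perm, k = 2)
  expect_equal(unname(cl_p$groups[names(cl$groups)] ==
                        cl_p$groups[["mir01"]]),
               unname(cl$groups[names(cl$groups)] == cl$groups[["mir01"]]))
  # newick export parses back to the same leaf set
  p <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, p)
  tree <- ape::read.tree(p)
  expect_setequal(tree$tip.label, rownames(corr$rho))
})

test_that("correlated_gene_lists applies the median + every-miRNA rule", {
  rho <- rbind(c(-0.5, -0.4, 0.2, 0.5),
               c(-0.6, -0.35, -0.05, 0.45),
               c(-0.4, 0.2, -0.3, 0.35))
  dimnames(rho) <- list(paste0("mir", 1:3), paste0("g", 1:4))
  corr <- structure(list(rho = rho, n_samples = 40), class = "correlation_matrix")
  grp <- c("mir1", "mir2")
  # g1, g2: medians -0.55 / -0.375, all rho < -0.1 -> negative list
  expect_equal(correlated_gene_lists(corr, grp, "negative"), c("g1", "g2"))
  # g4: median 0.475, all > 0.1 -> positive list
  expect_equal(correlated_gene_lists(corr, grp, "positive"), "g4")
  # g2 passes with mir1+mir2 but mir3 at +0.2 breaks the consistency rule
  expect_false("g2" %in% correlated_gene_lists(corr, paste0("mir", 1:3), "negative"))
  # growing the group can only shrink the lists
  small <- correlated_gene_lists(corr, "mir1", "negative")
  big <- correlated_gene_lists(corr, paste0("mir", 1:3), "negative")
  expect_true(all(big %in% small))
  # disjoint directions
  expect_length(intersect(correlated_gene_lists(corr, grp, "negative"),
                          correlated_gene_lists(corr, grp, "positive")), 0)
  # brute-force oracle on a random grid
  set.seed(123)
  rho2 <- matrix(runif(6 * 50, -1, 1), nrow = 6,
                 dimnames = list(paste0("m", 1:6), paste0("g", 1:50)))
  corr2 <- structure(list(rho = rho2, n_samples = 40),
                     class = "correlation_matrix")
  grp2 <- paste0("m", 1:3)
  brute <- colnames(rho2)[apply(rho2[grp2, ], 2, median) < -0.3 &
                            colSums(rho2[grp2, ] < -0.1) == 3]
  expect_equal(correlated_gene_lists(corr2, grp2, "negative"), brute)
  expect_error(correlated_gene_lists(corr2, character(0), "negative"), "empty")
  expect_error(correlated_gene_lists(corr2, grp2, "negative",
                                     median_threshold = 0.1,
                                     individual_threshold = 0.3), "individual")
})

test_that("target_sign_balance counts significant taus and tests balance", {
  set.seed(124)
  n <- 30
  x <- rpois(n, 500)
  mir <- toy_counts(matrix(x, 1), "normalized", features = "mirX")
  # 6 strongly negative, 2 strongly positive, 4 noise targets
  g <- rbind(
    t(replicate(6, max(x) - x + rpois(n, 5))),
    t(replicate(2, x + rpois(n, 5))),
    t(replicate(4, rpois(n, 300)))
  )
  gene <- toy_counts(g, "normalized", features = paste0("t", 1:12))
  map <- data.frame(mirna_id = "mirX", gene_id = paste0("t", 1:12),
                    evidence = "high")
  res <- target_sign_balance("mirX", map, mir, gene)
  expect_gte(res$n_negative, 6)
  expect_gte(res$n_positive, 2)
  expect_equal(res$test$p_value,
               binomial_two_sided(min(res$n_negative, res$n_positive),
                                  res$n_negative + res$n_positive)$p_value)
  expect_error(target_sign_balance("mirX", map[0, ], mir, gene), "targets")
})

test_that("hypergeometric_enrichment matches the combinatorial oracle", {
  background <- paste0("g", 1:40)
  sets <- list(S1 = paste0("g", 1:10), S2 = paste0("g", 11:30),
               OUT = paste0("h", 1:5))
  query <- paste0("g", 1:8)
  res <- hypergeometric_enrichment(query, sets, background)
  expect_false("OUT" %in% res$set_id)   # empty after background intersection
  # direct mass summation oracle
  oracle <- function(k, K, N, n) {
    sum(vapply(k:min(K, n), function(i) {
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
    }, 0))
  }
  r1 <- res[res$set_id == "S1", ]
  expect_equal(r1$p_value, oracle(r1$query_hits, r1$set_size, 40, 8),
               tolerance = 1e-12)
  # query equal to a full set is the most enriched
  res2 <- hypergeometric_enrichment(paste0("g", 1:10), sets, background)
  expect_equal(res2$set_id[which.min(res2$p_value)], "S1")
  expect_true(all(res2$query_hits <= pmin(res2$set_size, res2$query_size)))
  # stray query genes rejected by name
  expect_error(hypergeometric_enrichment(c("g1", "nope"), sets, background),
               "nope")
  # null calibration: uniform queries give roughly nominal significance
  set.seed(125)
  bg <- paste0("x", 1:2000)
  big_sets <- lapply(1:40, function(i) sample(bg, 300))
  names(big_sets) <- paste0("B", 1:40)
  hits <- replicate(25, {
    q <- sample(bg, 250)
    mean(hypergeometric_enrichment(q, big_sets, bg)$p_value < 0.05)
  })
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.10)
})
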