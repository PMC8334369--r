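mk_annot <- function(ids, chrom, start, end) {
  placentamir:::new_annotation(data.frame(
    feature_id = ids, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = "+", cluster = "other"))
}

test_that("enumerate_pairs applies the half-open +/-100kb window", {
  annot <- mk_annot("mirA", "chr1", 1e6, 1e6 + 1000)
  dose <- matrix(rep(1, 4 * 4), nrow = 4)
  g <- toy_genotypes(dose, chrom = "chr1",
                     pos = c(900000L, 899999L, 1100999L, 1101000L))
  pairs <- enumerate_pairs(g, annot, flank = 1e5)
  # left edge inclusive (900000 = start - flank), right edge exclusive
  expect_setequal(pairs$snv_id, c("snv1", "snv3"))
  # other chromosome never pairs
  g2 <- toy_genotypes(dose, chrom = "chr2", pos = rep(1e6, 4))
  expect_equal(nrow(enumerate_pairs(g2, annot)), 0)
  # monotone in flank
  expect_lte(nrow(enumerate_pairs(g, annot, flank = 5e4)),
             nrow(enumerate_pairs(g, annot, flank = 1e5)))
  # brute-force oracle on random positions
  set.seed(131)
  pos <- sample(1e5:2e6, 200)
  gr <- toy_genotypes(matrix(1, 200, 4), chrom = "chr1", pos = pos)
  st <- sample(2e5:18e5, 10)
  annot2 <- mk_annot(paste0("m", 1:10), "chr1", start = st, end = st + 2e3)
  got <- enumerate_pairs(gr, annot2, flank = 1e5)
  brute <- do.call(rbind, lapply(1:10, function(i) {
    hit <- pos >= annot2$start[i] - 1e5 & pos < annot2$end[i] + 1e5
    if (!any(hit)) return(NULL)
    data.frame(snv_id = paste0("snv", which(hit)),
               mirna_id = annot2$feature_id[i])
  }))
  expect_equal(nrow(got), nrow(brute))
  expect_setequal(paste(got$snv_id, got$mirna_id),
                  paste(brute$snv_id, brute$mirna_id))
})

test_that("maf_hwe_filter applies strict MAF > threshold and reports HWE", {
  # rows: monomorphic; MAF exactly 0.10 (8/80); MAF 0.2
  n <- 40
  d1 <- rep(0, n)
  d2 <- c(rep(1, 8), rep(0, n - 8))
  d3 <- c(rep(1, 16), rep(0, n - 16))
  g <- toy_genotypes(rbind(d1, d2, d3))
  out <- maf_hwe_filter(g, maf_min = 0.1)
  expect_equal(out$report$maf, c(0, 0.1, 0.2))
  expect_equal(out$report$kept, c(FALSE, FALSE, TRUE))
  expect_equal(rownames(out$genotypes$dosages), "snv3")
  expect_true(all(out$report$hwe_p[out$report$kept] >= 0 &
                    out$report$hwe_p[out$report$kept] <= 1))
  # simulated HWE genotypes are not flagged
  set.seed(132)
  sim <- t(replicate(300, rbinom(60, 1, 0.3) + rbinom(60, 1, 0.3)))
  gs <- toy_genotypes(sim)
  rep_ <- maf_hwe_filter(gs, maf_min = 0.05)$report
  expect_lt(mean(rep_$hwe_p < 0.05, na.rm = TRUE), 0.08)
  expect_gt(median(rep_$hwe_p, na.rm = TRUE), 0.25)
  # optional HWE exclusion threshold drops violators
  viol <- rbind(c(rep(1, 38), 0, 0))   # het excess
  gv <- toy_genotypes(viol)
  expect_false(maf_hwe_filter(gv, 0.1, hwe_alpha = 0.05)$report$kept)
})

eqtl_world <- function(n = 40, beta = 50, maf = 0.3, sd = 20, seed = 1) {
  set.seed(seed)
  dose <- rbinom(n, 1, maf) + rbinom(n, 1, maf)
  meta <- two_group_meta(n / 2)
  sex <- as.numeric(meta$fetal_sex == "XY")
  y <- 500 + beta * dose + 5 * sex + rnorm(n, sd = sd)
  expr <- toy_counts(matrix(pmax(y, 0), 1), "normalized", features = "mirA")
  g <- toy_genotypes(matrix(dose, 1), chrom = "chr1", pos = 1000100L)
  list(expr = expr, geno = g, meta = meta, dose = dose)
}

test_that("eqtl_scan recovers a planted effect and handles degenerate dosages", {
  w <- eqtl_world(seed = 133)
  annot <- mk_annot("mirA", "chr1", 1e6, 1e6 + 200)
  pairs <- enumerate_pairs(w$geno, annot)
  expect_equal(nrow(pairs), 1)
  res <- eqtl_scan(w$expr, w$geno, w$meta, pairs)
  expect_equal(nrow(res), 1)
  expect_lt(abs(res$beta - 50), 3 * res$se)
  expect_lt(res$p_value, 1e-4)
  expect_true(!is.na(res$maf) && !is.na(res$hwe_p))
  # flipping the dosage coding negates beta, p unchanged
  g_flip <- w$geno; g_flip$dosages <- 2 - g_flip$dosages
  res_f <- eqtl_scan(w$expr, g_flip, w$meta, pairs)
  expect_equal(res_f$beta, -res$beta, tolerance = 1e-10)
  expect_equal(res_f$p_value, res$p_value, tolerance = 1e-10)
  # constant dosage -> skipped with a reason
  g_const <- w$geno; g_const$dosages[1, ] <- 1
  res_c <- eqtl_scan(w$expr, g_const, w$meta, pairs)
  expect_equal(nrow(res_c), 0)
  expect_equal(attr(res_c, "skipped")$reason, "constant_dosage")
  # too few complete cases -> skipped
  g_na <- w$geno; g_na$dosages[1, 1:35] <- NA
  res_n <- eqtl_scan(w$expr, g_na, w$meta, pairs)
  expect_equal(attr(res_n, "skipped")$reason, "too_few_complete_cases")
})

test_that("permuted genotypes yield a null scan", {
  set.seed(134)
  n <- 40
  meta <- two_group_meta(n / 2)
  expr <- toy_counts(matrix(rpois(5 * n, 400), 5), "normalized",
                     features = paste0("m", 1:5))
  dose <- t(replicate(40, rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)))
  g <- toy_genotypes(dose, chrom = "chr1", pos = seq(1e6, by = 5e3, length.out = 40))
  annot <- mk_annot(paste0("m", 1:5), "chr1",
                    start = seq(1e6, by = 4e4, length.out = 5),
                    end = seq(1e6, by = 4e4, length.out = 5) + 200)
  pairs <- enumerate_pairs(g, annot)
  res <- eqtl_scan(expr, g, meta, pairs)
  expect_gt(nrow(res), 50)
  expect_equal(sum(res$fdr < 0.05), 0)
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
})

test_that("trait_association fits linear and logistic additive models", {
  set.seed(135)
  n <- 300
  meta <- two_group_meta(n / 2)
  dose <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)
  meta$weight <- 3500 + 200 * dose + rnorm(n, sd = 300)
  meta$flag <- rbinom(n, 1, plogis(-1 + 0.8 * dose))
  g <- toy_genotypes(matrix(dose, 1))
  res <- trait_association(meta, g, c("weight", "flag"))
  expect_equal(res$model[res$trait == "weight"], "linear")
  expect_equal(res$model[res$trait == "flag"], "logistic")
  expect_lt(abs(res$beta[res$trait == "weight"] - 200),
            3 * res$se[res$trait == "weight"])
  expect_lt(abs(res$beta[res$trait == "flag"] - 0.8),
            3 * res$se[res$trait == "flag"])
  # one-class binary trait rejected
  meta$allzero <- 0
  expect_error(trait_association(meta, g, "allzero"), "single class")
  # null trait: type-I near nominal over replicates
  rej <- mean(replicate(200, {
    meta$null_tr <- rnorm(n)
    trait_association(meta, g, "null_tr")$p_value < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("meta_across_cohorts pools shared pairs by inverse variance", {
  r1 <- data.frame(snv_id = c("s1", "s2"), trait = "wt",
                   beta = c(1, 0.5), se = c(0.2, 0.3))
  r2 <- data.frame(snv_id = c("s1", "s2"), trait = "wt",
                   beta = c(1, -0.5), se = c(0.2, 0.3))
  m <- meta_across_cohorts(list(r1, r2))
  # identical results: beta unchanged, se shrunk by sqrt(2)
  s1 <- m[m$snv_id == "s1", ]
  expect_equal(s1$pooled_beta, 1, tolerance = 1e-12)
  expect_equal(s1$pooled_se, 0.2 / sqrt(2), tolerance = 1e-12)
  # opposite equal-weight betas cancel
  expect_equal(m$pooled_beta[m$snv_id == "s2"], 0, tolerance = 1e-12)
  # three cohorts against hand-computed pooling
  r3 <- data.frame(snv_id = "s1", trait = "wt", beta = 2, se = 0.5)
  m3 <- meta_across_cohorts(list(r1, r2, r3), min_cohorts = 2)
  w <- 1 / c(0.2, 0.2, 0.5)^2
  expect_equal(m3$pooled_beta[m3$snv_id == "s1"],
               sum(w * c(1, 1, 2)) / sum(w), tolerance = 1e-10)
  # pairs below min_cohorts are dropped
  expect_true("s2" %in% m3$snv_id)   # present in 2 of 3
  m_strict <- meta_across_cohorts(list(r1, r2, r3))
  expect_false("s2" %in% m_strict$snv_id)
})
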