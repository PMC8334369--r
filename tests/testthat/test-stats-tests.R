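# Statistical primitives against independent oracles: brute-force BH,
# base-R reference tests, Monte-Carlo permutation nulls, closed forms.

bh_oracle <- function(p) {
  # direct step-up definition: adj_(i) = min_{j >= i} p_(j) * n / j
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(n), function(i) {
    min(1, min(sorted[i:n] * n / (i:n)))
  }, 0)
  out <- numeric(n)
  out[o] <- adj
  out
}

test_that("bh_adjust matches the brute-force step-up oracle and base R", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    got <- bh_adjust(p)
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
    expect_equal(got, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15))
    expect_true(all(got <= 1))
    # monotone in the sorted order of raw p
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.2, 1.3)), "index 2")
  expect_error(bh_adjust(c(0.2, NA)), "missing")
})

test_that("binomial_two_sided reproduces the reported sign-balance p-values", {
  expect_equal(binomial_two_sided(8, 29)$p_value, 0.024, tolerance = 0.02)
  expect_gt(binomial_two_sided(7, 16)$p_value, 0.58)
  expect_gt(binomial_two_sided(5, 13)$p_value, 0.58)
  expect_equal(binomial_two_sided(0, 1)$p_value, 1)
  expect_equal(binomial_two_sided(5, 10)$p_value, 1)
})

test_that("binomial_two_sided agrees with binom.test at p0 = 0.5 and is symmetric", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    expect_equal(binomial_two_sided(k, n)$p_value,
                 binom.test(k, n)$p.value, tolerance = 1e-12)
    expect_equal(binomial_two_sided(k, n)$p_value,
                 binomial_two_sided(n - k, n)$p_value, tolerance = 1e-12)
  }
  expect_error(binomial_two_sided(1, 0), "n")
  expect_error(binomial_two_sided(5, 3), "k")
})

test_that("chi2_independence matches the printed target-count p and reference", {
  tab <- matrix(c(1305, 773, 1207, 888), nrow = 2, byrow = TRUE)
  got <- chi2_independence(tab)
  expect_equal(signif(got$p_value, 2), 6.2e-4)
  expect_equal(got$p_value,
               chisq.test(tab, correct = FALSE)$p.value, tolerance = 1e-12)
  # Yates only on request, and it moves the p-value
  expect_equal(chi2_independence(tab, yates = TRUE)$p_value,
               chisq.test(tab, correct = TRUE)$p.value, tolerance = 1e-12)
  # identical rows: exact independence
  same <- matrix(c(5, 10, 5, 10), 2, byrow = TRUE)
  expect_equal(chi2_independence(same)$statistic, 0)
  expect_equal(chi2_independence(same)$p_value, 1)
  expect_error(chi2_independence(matrix(c(0, 0, 1, 2), 2)), "marginal")
})

test_that("chi2_independence is permutation/transpose invariant and matches a Monte-Carlo null", {
  set.seed(31)
  m <- matrix(rpois(6, 80), nrow = 2)
  base <- chi2_independence(m)
  expect_equal(chi2_independence(m[, c(3, 1, 2)])$statistic, base$statistic)
  expect_equal(chi2_independence(m[c(2, 1), ])$statistic, base$statistic)
  expect_equal(chi2_independence(t(m))$statistic, base$statistic)
  # permutation oracle: r2dtable-based MC with large counts where the
  # asymptotic p is accurate
  big <- matrix(c(120, 95, 88, 117), 2)
  mc <- chisq.test(big, correct = FALSE, simulate.p.value = TRUE, B = 1e5)
  expect_equal(chi2_independence(big)$p_value, mc$p.value, tolerance = 0.02)
})

test_that("kruskal_wallis matches base R with ties and holds its size", {
  g <- list(c(1, 2, 2, 3), c(2, 2, 4, 5, 5), c(0, 1, 1))
  got <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # two-group case against the same reference (rank-sum equivalent)
  g2 <- list(rnorm(7), rnorm(9) + 1)
  expect_equal(kruskal_wallis(g2)$p_value,
               kruskal.test(unlist(g2), rep(1:2, lengths(g2)))$p.value,
               tolerance = 1e-12)
  # identical constant groups
  flat <- kruskal_wallis(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  # size under the null
  set.seed(41)
  rej <- mean(replicate(2000, {
    kruskal_wallis(list(rnorm(6), rnorm(6), rnorm(6)))$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

hwe_dist <- function(n_a, n) {
  # closed-form conditional distribution of the het count given allele
  # counts, computed with plain factorial arithmetic
  hets <- seq(n_a %% 2, n_a, by = 2)
  num <- vapply(hets, function(h) {
    exp(lfactorial(n) - lfactorial((2 * n - n_a - h) / 2) - lfactorial(h) -
          lfactorial((n_a - h) / 2) + h * log(2))
  }, 0)
  data.frame(het = hets, prob = num / sum(num))
}

test_that("hwe_exact matches full enumeration and a Monte-Carlo pairing oracle", {
  # enumeration oracle
  for (case in list(c(25, 50, 25), c(10, 21, 5), c(3, 1, 3))) {
    n <- sum(case)
    n_a <- min(2 * case[3] + case[2], 2 * case[1] + case[2])
    d <- hwe_dist(n_a, n)
    obs <- d$prob[d$het == case[2]]
    expect_equal(hwe_exact(case[1], case[2], case[3])$p_value,
                 sum(d$prob[d$prob <= obs * (1 + 1e-9)]), tolerance = 1e-9)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  }
  # monomorphic: single configuration
  expect_equal(hwe_exact(0, 0, 12)$p_value, 1)
  # heterozygote excess with many of each allele is detected
  expect_lt(hwe_exact(0, 40, 0)$p_value, 0.05)
  # Monte-Carlo oracle: random pairing of the allele pool
  set.seed(51)
  case <- c(14, 10, 6)
  n <- sum(case); n_a <- 2 * case[3] + case[2]
  pool <- c(rep(1, n_a), rep(0, 2 * n - n_a))
  obs_d <- hwe_dist(min(n_a, 2 * n - n_a), n)
  p_obs <- obs_d$prob[obs_d$het == case[2]]
  mc <- replicate(2e4, {
    pairs <- matrix(sample(pool), ncol = 2)
    h <- sum(pairs[, 1] != pairs[, 2])
    obs_d$prob[obs_d$het == h] <= p_obs * (1 + 1e-9)
  })
  expect_lt(abs(hwe_exact(case[1], case[2], case[3])$p_value - mean(mc)), 0.02)
})

test_that("fixed_effect_meta pools by inverse variance", {
  one <- fixed_effect_meta(0.3, 0.1)
  expect_equal(one$pooled_beta, 0.3)
  expect_equal(one$pooled_se, 0.1)
  two <- fixed_effect_meta(c(1, 1), c(1, 1))
  expect_equal(two$pooled_beta, 1)
  expect_equal(two$pooled_se, 1 / sqrt(2), tolerance = 1e-12)
  # hand-computed heterogeneous pooling
  b <- c(0.2, -0.1, 0.5); s <- c(0.1, 0.2, 0.05)
  w <- 1 / s^2
  got <- fixed_effect_meta(b, s)
  expect_equal(got$pooled_beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(got$pooled_se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(sum(got$study_weights), 1, tolerance = 1e-9)
  expect_lte(got$pooled_se, min(s))
  expect_error(fixed_effect_meta(c(1, 2), c(1, 0)), "positive")
})
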