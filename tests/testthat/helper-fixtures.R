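# Shared builders for in-code fixtures. Everything is generated at test
# time; no binary data ships with the package.

toy_counts <- function(values, kind = "raw",
                       features = sprintf("f%d", seq_len(nrow(values))),
                       samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  count_matrix(values, kind)
}

# minimal valid sample table for two term groups of size n each
two_group_meta <- function(n, groups = c("NORM", "PE")) {
  k <- n * length(groups)
  data.frame(
    sample_id = sprintf("s%d", seq_len(k)),
    trimester = "term",
    gestational_days = 270L + seq_len(k) %% 10,
    fetal_sex = rep(c("XX", "XY"), length.out = k),
    group = rep(groups, each = n),
    stringsAsFactors = FALSE
  )
}

# NB count matrix for a two-group null or shifted design
sim_nb_counts <- function(n_features, n_per_group, mu_log = log(300),
                          mu_sd = 1, alpha = 0.1, log2fc = 0) {
  n <- 2 * n_per_group
  base <- rlnorm(n_features, mu_log, mu_sd)
  mu <- outer(base, rep(1, n))
  mu[, seq(n_per_group + 1, n)] <- mu[, seq(n_per_group + 1, n)] * 2^log2fc
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha),
                nrow = n_features)
  toy_counts(cnt)
}

# genotype matrix straight from dosages
toy_genotypes <- function(dosages, chrom = "chr1",
                          pos = seq_len(nrow(dosages)) * 1000L) {
  snv_id <- sprintf("snv%d", seq_len(nrow(dosages)))
  colnames(dosages) <- sprintf("s%d", seq_len(ncol(dosages)))
  placentamir:::new_genotypes(
    dosages,
    data.frame(snv_id = snv_id, chrom = chrom, pos = as.integer(pos),
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  )
}
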