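# Synthetic cohort generator. Emulates the statistical structure the
# pipeline assumes: NB-distributed miRNA/gene counts for a 52-sample
# design (5 first-trimester, 7 second-trimester, 5 x 8 term clinical
# groups), planted nine-pattern gestational dynamics with log2FC drawn
# from the observed range, a PE expression shift in a chosen miRNA subset,
# contiguous imprinted miRNA blocks on chr19/chr14, HWE genotypes with
# additive cis effects on miRNA log-means, genes tied to miRNA latent
# profiles with planted correlation signs, and continuous/binary pregnancy
# traits. Every draw flows from the single seed in the config.

#' Simulation configuration
#'
#' Defaults encode the cohort design this pipeline targets: sample sizes
#' 5/7/8-per-term-group, nine-pattern proportions matching the observed
#' pattern table, log2 fold changes within \[-4.91, 2.84\], a 16% PE DEmiR
#' fraction, and NB dispersion 0.05.
#'
#' @param seed integer seed (mandatory).
#' @param n_t1,n_t2,n_term_per_group sample sizes (defaults 5, 7, 8).
#' @param n_mirnas,n_genes,n_snvs feature counts (defaults 50, 300, 100).
#' @param pattern_proportions named probabilities over the nine patterns.
#' @param log2fc_range planted transition log2FC range.
#' @param effect_floor minimum |log2FC| of a planted Up/Down transition.
#' @param pe_demir_fraction fraction of miRNAs shifted in PE placentas.
#' @param pe_shift_range |log2| shift range applied to PE samples.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param library_size_range per-sample library size range (uniform).
#' @param cluster_block_sizes named sizes of the C19MC / C14MC /
#'   miR371_373 genomic blocks.
#' @param n_planted_eqtl number of planted cis eQTLs.
#' @param eqtl_beta,eqtl_maf planted eQTL effect (log-mean units per minor
#'   allele copy) and MAF.
#' @param n_corr_genes genes planted per correlation direction.
#' @param corr_strength latent-signal strength of planted gene-miRNA pairs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_t1 = 5L, n_t2 = 7L, n_term_per_group = 8L,
                       n_mirnas = 50L, n_genes = 300L, n_snvs = 100L,
                       pattern_proportions = NULL,
                       log2fc_range = c(-4.91, 2.84),
                       effect_floor = 1,
                       pe_demir_fraction = 0.16,
                       pe_shift_range = c(0.8, 1.4),
                       dispersion = 0.05,
                       library_size_range = c(8e5, 1.2e6),
                       cluster_block_sizes = c(C19MC = 8L, C14MC = 7L,
                                               miR371_373 = 2L),
                       n_planted_eqtl = 5L,
                       eqtl_beta = 0.7, eqtl_maf = 0.3,
                       n_corr_genes = 30L,
                       corr_strength = 0.8) {
  if (missing(seed) || is.na(seed)) stop("sim_config: seed is mandatory")
  if (is.null(pattern_proportions)) {
    # empirical nine-pattern composition of a 417-miRNA placental cohort
    counts <- c("Down-Down" = 30, "Down-NoChange" = 67, "Down-Up" = 28,
                "Up-Up" = 35, "Up-NoChange" = 41, "Up-Down" = 26,
                "NoChange-Down" = 54, "NoChange-Up" = 38,
                "NoChange-NoChange" = 98)
    pattern_proportions <- counts / sum(counts)
  }
  if (abs(sum(pattern_proportions) - 1) > 1e-8) {
    stop("sim_config: pattern_proportions must sum to 1")
  }
  if (!setequal(names(pattern_proportions), PATTERN_LEVELS)) {
    stop("sim_config: pattern_proportions must be named by the nine patterns")
  }
  if (eqtl_maf <= 0 || eqtl_maf > 0.5) stop("sim_config: MAF must be in (0, 0.5]")
  if (sum(cluster_block_sizes) > n_mirnas) {
    stop("sim_config: cluster blocks exceed n_mirnas")
  }
  structure(as.list(environment()), class = "sim_config")
}

trimester_day_range <- function(tri) {
  switch(tri, "1" = c(51, 81), "2" = c(108, 140), "term" = c(260, 291))
}

# term birth-trait means by clinical group: (weight g, length cm, head cm,
# chest cm, placental weight g)
TRAIT_MEANS <- list(
  NORM = c(3756, 51, 36, 35, 575), PE = c(2803, 48, 34, 31, 463),
  GD = c(4284, 53, 36, 36, 588), SGA = c(2517, 46, 32, 31, 420),
  LGA = c(4744, 53, 38, 37, 818)
)
TRAIT_SDS <- c(350, 1.5, 1.2, 1.5, 90)
TRAIT_NAMES <- c("birth_weight", "birth_length", "head_circumference",
                 "chest_circumference", "placental_weight")

rnb <- function(n, mu, alpha) {
  if (alpha < 1e-8) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate a complete in-silico cohort
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle`: `mirna_counts`, `gene_counts` (raw
#'   [count_matrix()]), `samples` (metadata data.frame), `annotation`
#'   (miRNA annotation), `genotypes` (`genotype_matrix`), `target_map`,
#'   `gene_sets` (list), `truth` (ground-truth record).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  ## ---- samples -------------------------------------------------------
  groups <- c(rep("T1", cfg$n_t1), rep("T2", cfg$n_t2),
              rep(c("NORM", "PE", "GD", "SGA", "LGA"),
                  each = cfg$n_term_per_group))
  tri <- ifelse(groups == "T1", "1", ifelse(groups == "T2", "2", "term"))
  n_samples <- length(groups)
  sample_id <- sprintf("S%02d_%s", seq_len(n_samples), groups)
  gdays <- vapply(tri, function(t) {
    r <- trimester_day_range(t); round(stats::runif(1, r[1], r[2]))
  }, 0)
  fetal_sex <- rep(c("XX", "XY"), length.out = n_samples)
  samples <- data.frame(sample_id = sample_id, trimester = tri,
                        gestational_days = as.integer(gdays),
                        fetal_sex = fetal_sex, group = groups,
                        stringsAsFactors = FALSE)
  for (j in seq_along(TRAIT_NAMES)) {
    v <- rep(NA_real_, n_samples)
    at_term <- tri == "term"
    mu <- vapply(groups[at_term], function(g) TRAIT_MEANS[[g]][j], 0)
    v[at_term] <- round(stats::rnorm(sum(at_term), mu, TRAIT_SDS[j]), 1)
    samples[[TRAIT_NAMES[j]]] <- v
  }
  samples$pe_diagnosis <- ifelse(tri == "term",
                                 as.integer(groups == "PE"), NA_integer_)
  samples$gd_diagnosis <- ifelse(tri == "term",
                                 as.integer(groups == "GD"), NA_integer_)

  ## ---- miRNA annotation: contiguous imprinted blocks -----------------
  mirna_id <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  bs <- cfg$cluster_block_sizes
  cluster <- rep("other", cfg$n_mirnas)
  chrom <- character(cfg$n_mirnas); start <- integer(cfg$n_mirnas)
  i <- 1L
  place_block <- function(n, chr, origin, spacing) {
    list(chrom = rep(chr, n),
         start = as.integer(origin + (seq_len(n) - 1L) * spacing))
  }
  for (cl in names(bs)) {
    n <- bs[[cl]]
    blk <- switch(cl,
      C19MC = place_block(n, "chr19", 53700000L, 12000L),
      C14MC = place_block(n, "chr14", 101000000L, 30000L),
      miR371_373 = place_block(n, "chr19", 58000000L, 400L))
    idx <- seq(i, i + n - 1L)
    cluster[idx] <- cl; chrom[idx] <- blk$chrom; start[idx] <- blk$start
    i <- i + n
  }
  rest <- seq(i, cfg$n_mirnas)
  chrom[rest] <- sprintf("chr%d", 1 + (seq_along(rest) - 1L) %% 12)
  start[rest] <- as.integer(1e6 + (seq_along(rest) - 1L) * 5e5)
  annotation <- new_annotation(data.frame(
    feature_id = mirna_id, chrom = chrom, start = start,
    end = start + 80L, strand = rep(c("+", "-"), length.out = cfg$n_mirnas),
    cluster = cluster, stringsAsFactors = FALSE
  ))

  ## ---- planted gestational dynamics ----------------------------------
  pat <- sample(names(cfg$pattern_proportions), cfg$n_mirnas, replace = TRUE,
                prob = cfg$pattern_proportions)
  draw_fc <- function(dir) {
    lo <- cfg$log2fc_range[1]; hi <- cfg$log2fc_range[2]
    switch(dir,
           Down = -stats::runif(1, cfg$effect_floor, abs(lo)),
           Up = stats::runif(1, cfg$effect_floor, hi),
           NoChange = 0)
  }
  parts <- strsplit(pat, "-", fixed = TRUE)
  fc1 <- vapply(parts, function(p) draw_fc(p[1]), 0)
  fc2 <- vapply(parts, function(p) draw_fc(p[2]), 0)

  ## ---- PE shift -------------------------------------------------------
  n_pe <- max(1L, round(cfg$pe_demir_fraction * cfg$n_mirnas))
  pe_idx <- sample(cfg$n_mirnas, n_pe)
  pe_shift <- numeric(cfg$n_mirnas)
  pe_shift[pe_idx] <- sample(c(-1, 1), n_pe, replace = TRUE) *
    stats::runif(n_pe, cfg$pe_shift_range[1], cfg$pe_shift_range[2])

  ## ---- genotypes and eQTL effects ------------------------------------
  snv_id <- sprintf("rs%06d", seq_len(cfg$n_snvs))
  eqtl_mirna_idx <- sample(cfg$n_mirnas, cfg$n_planted_eqtl)
  snv_chrom <- character(cfg$n_snvs); snv_pos <- integer(cfg$n_snvs)
  maf <- stats::runif(cfg$n_snvs, 0.05, 0.5)
  # planted eQTL SNVs sit inside the cis window of their miRNA
  for (k in seq_len(cfg$n_planted_eqtl)) {
    m <- eqtl_mirna_idx[k]
    snv_chrom[k] <- annotation$chrom[m]
    snv_pos[k] <- annotation$start[m] + sample(-5e4:5e4, 1)
    maf[k] <- cfg$eqtl_maf
  }
  # half the rest are cis to random miRNAs, half far away
  rest <- seq(cfg$n_planted_eqtl + 1L, cfg$n_snvs)
  for (k in rest) {
    if (k %% 2 == 0) {
      m <- sample(cfg$n_mirnas, 1)
      snv_chrom[k] <- annotation$chrom[m]
      snv_pos[k] <- annotation$start[m] + sample(-9e4:9e4, 1)
    } else {
      snv_chrom[k] <- sprintf("chr%d", 1 + (k %% 20))
      snv_pos[k] <- as.integer(5e7 + k * 1e4)
    }
  }
  dosages <- t(vapply(maf, function(f) {
    stats::rbinom(n_samples, 1, f) + stats::rbinom(n_samples, 1, f)
  }, numeric(n_samples)))
  colnames(dosages) <- sample_id
  geno_info <- data.frame(snv_id = snv_id, chrom = snv_chrom, pos = snv_pos,
                          ref = "A", alt = "G", minor_is_ref = FALSE,
                          stringsAsFactors = FALSE)
  genotypes <- new_genotypes(dosages, geno_info)
  eqtl_truth <- data.frame(
    snv_id = snv_id[seq_len(cfg$n_planted_eqtl)],
    mirna_id = mirna_id[eqtl_mirna_idx],
    beta = cfg$eqtl_beta, maf = cfg$eqtl_maf, stringsAsFactors = FALSE
  )

  ## ---- miRNA counts ---------------------------------------------------
  base_mu <- stats::rlnorm(cfg$n_mirnas, log(300), 1.2)
  tri_mult <- rbind("1" = rep(0, cfg$n_mirnas), "2" = fc1, "term" = fc1 + fc2)
  lib <- stats::runif(n_samples, cfg$library_size_range[1],
                      cfg$library_size_range[2])
  lib_scale <- lib / stats::median(lib)
  log_mu <- matrix(0, cfg$n_mirnas, n_samples,
                   dimnames = list(mirna_id, sample_id))
  for (j in seq_len(n_samples)) {
    log_mu[, j] <- log(base_mu) + log(2) * tri_mult[tri[j], ] +
      log(2) * pe_shift * (groups[j] == "PE") + log(lib_scale[j])
  }
  for (k in seq_len(cfg$n_planted_eqtl)) {
    m <- eqtl_mirna_idx[k]
    log_mu[m, ] <- log_mu[m, ] + cfg$eqtl_beta * dosages[k, ]
  }
  mirna_counts <- matrix(
    rnb(length(log_mu), exp(log_mu), cfg$dispersion),
    nrow = cfg$n_mirnas, dimnames = dimnames(log_mu)
  )

  ## ---- genes: planted latent correlation -----------------------------
  gene_id <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  gene_base <- stats::rlnorm(cfg$n_genes, log(500), 1)
  n_corr <- min(cfg$n_corr_genes, floor(cfg$n_genes / 2))
  corr_mirna <- sample(cfg$n_mirnas, 2 * n_corr, replace = TRUE)
  corr_sign <- rep(c(1, -1), each = n_corr)
  corr_truth <- data.frame(
    gene_id = gene_id[seq_len(2 * n_corr)],
    mirna_id = mirna_id[corr_mirna],
    direction = ifelse(corr_sign > 0, "positive", "negative"),
    strength = cfg$corr_strength, stringsAsFactors = FALSE
  )
  log_mu_g <- matrix(rep(log(gene_base), n_samples), ncol = n_samples,
                     dimnames = list(gene_id, sample_id))
  log_mu_g <- sweep(log_mu_g, 2, log(lib_scale), "+")
  latent <- t(scale(t(log_mu)))   # per-miRNA standardized latent profile
  for (r in seq_len(2 * n_corr)) {
    log_mu_g[r, ] <- log_mu_g[r, ] +
      corr_sign[r] * 1.5 * cfg$corr_strength * latent[corr_mirna[r], ]
  }
  gene_counts <- matrix(
    rnb(length(log_mu_g), exp(log_mu_g), cfg$dispersion),
    nrow = cfg$n_genes, dimnames = dimnames(log_mu_g)
  )

  ## ---- target map and gene sets --------------------------------------
  target_map <- rbind(
    data.frame(mirna_id = corr_truth$mirna_id, gene_id = corr_truth$gene_id,
               evidence = "high", stringsAsFactors = FALSE),
    data.frame(mirna_id = mirna_id[sample(cfg$n_mirnas, 40, replace = TRUE)],
               gene_id = gene_id[sample(cfg$n_genes, 40, replace = TRUE)],
               evidence = "high", stringsAsFactors = FALSE)
  )
  target_map <- unique(target_map)
  neg_genes <- corr_truth$gene_id[corr_truth$direction == "negative"]
  gene_sets <- list(
    PLANTED_NEGATIVE = neg_genes,
    PLANTED_POSITIVE = corr_truth$gene_id[corr_truth$direction == "positive"],
    RANDOM_SET_A = sort(sample(gene_id, 25)),
    RANDOM_SET_B = sort(sample(gene_id, 40))
  )

  structure(list(
    mirna_counts = count_matrix(mirna_counts, "raw"),
    gene_counts = count_matrix(gene_counts, "raw"),
    samples = validate_sample_table(samples),
    annotation = annotation,
    genotypes = genotypes,
    target_map = target_map,
    gene_sets = gene_sets,
    truth = list(
      pattern = stats::setNames(pat, mirna_id),
      log2fc_t1_t2 = stats::setNames(fc1, mirna_id),
      log2fc_t2_term = stats::setNames(fc2, mirna_id),
      pe_shift = stats::setNames(pe_shift, mirna_id),
      eqtl = eqtl_truth,
      correlation = corr_truth,
      dispersion = cfg$dispersion,
      library_sizes = stats::setNames(lib, sample_id)
    ),
    config = cfg
  ), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("sim_bundle: %d miRNAs, %d genes, %d SNVs, %d samples ",
                     "(seed %d)\n"),
              nrow(x$mirna_counts$values), nrow(x$gene_counts$values),
              nrow(x$genotypes$dosages), ncol(x$mirna_counts$values),
              x$config$seed))
  invisible(x)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, "na", sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a simulated bundle to disk
#'
#' Writes every component in its standard text format (TSV counts and
#' metadata, BED annotation, VCF genotypes, TSV target map, GMT gene
#' sets, JSON ground truth) so the pipeline can be driven from files.
#'
#' @param bundle a `sim_bundle`.
#' @param directory output directory (created if needed).
#' @return named vector of written paths.
#' @export
export_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_counts(bundle$mirna_counts, p("mirna_counts.tsv"))
  write_counts(bundle$gene_counts, p("gene_counts.tsv"))
  write_sample_table(bundle$samples, p("samples.tsv"))
  write_annotation_bed(bundle$annotation, p("mirna_annotation.bed"))
  write_genotypes_vcf(bundle$genotypes, p("genotypes.vcf"))
  utils::write.table(bundle$target_map, p("targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
  jsonlite::write_json(bundle$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  out <- c(mirna_counts = p("mirna_counts.tsv"),
           gene_counts = p("gene_counts.tsv"),
           samples = p("samples.tsv"),
           annotation = p("mirna_annotation.bed"),
           genotypes = p("genotypes.vcf"),
           targets = p("targets.tsv"),
           gene_sets = p("gene_sets.gmt"),
           truth = p("truth.json"))
  invisible(out)
}

#' Load an exported fixture directory
#'
#' Inverse of [export_fixture()] for the components the pipeline consumes
#' (the truth record is reloaded from JSON when present).
#'
#' @param directory fixture directory.
#' @return list with the same component names as a `sim_bundle`.
#' @export
read_fixture <- function(directory) {
  p <- function(f) file.path(directory, f)
  truth <- if (file.exists(p("truth.json"))) {
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  }
  list(
    mirna_counts = read_counts(p("mirna_counts.tsv"), "raw"),
    gene_counts = read_counts(p("gene_counts.tsv"), "raw"),
    samples = read_sample_table(p("samples.tsv")),
    annotation = read_annotation(p("mirna_annotation.bed"), "bed"),
    genotypes = read_genotypes_vcf(p("genotypes.vcf")),
    target_map = read_target_map(p("targets.tsv")),
    gene_sets = read_gmt(p("gene_sets.gmt")),
    truth = truth
  )
}
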