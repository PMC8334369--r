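# End-to-end orchestration: plain files plus a JSON manifest. Each stage
# reads its inputs from the result directory, writes its outputs there,
# and records row counts in the manifest; rerunning with the same config
# and seed reproduces every file byte-for-byte.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = TRUE,
    input_dir = NULL,
    alpha = 0.05,
    median_threshold = 50,
    flank = 1e5,
    maf_min = 0.1,
    median_rho_threshold = 0.3,
    individual_rho_threshold = 0.1,
    k_groups = 5L,
    de_covariates = NULL,
    sim = list()
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, checks threshold positivity and, when running from
#' files, that every referenced input exists.
#'
#' @param config named list or path to a JSON config file.
#' @return validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("pipeline_config: file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  with(cfg, {
    stopifnot(alpha > 0, median_threshold > 0, flank >= 0, maf_min > 0,
              median_rho_threshold > 0, individual_rho_threshold > 0,
              k_groups >= 1)
  })
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$input_dir)) {
      stop("pipeline_config: either simulate = TRUE or input_dir is required")
    }
    need <- c("mirna_counts.tsv", "gene_counts.tsv", "samples.tsv",
              "mirna_annotation.bed", "genotypes.vcf", "targets.tsv",
              "gene_sets.gmt")
    miss <- need[!file.exists(file.path(cfg$input_dir, need))]
    if (length(miss)) {
      stop("pipeline_config: missing input file(s): ",
           paste(miss, collapse = ", "))
    }
  }
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess -> de -> dynamics ->
#' correlate -> enrich -> eqtl -> associate -> meta, writing per-stage TSV
#' outputs and a JSON manifest (seed, input checksums, per-stage row
#' counts) under `out_dir`. Any stage failure aborts with the stage name.
#'
#' The meta stage demonstrates the two-cohort replication design on
#' simulated data by splitting the term samples into two deterministic
#' pseudo-cohorts and pooling their trait associations.
#'
#' @param config list or JSON path, see [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("placentamir")),
                   seed = cfg$seed, stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- res
    res
  }
  p <- function(f) file.path(out_dir, f)

  ## simulate -----------------------------------------------------------
  bundle <- NULL
  stage("simulate", function() {
    if (isTRUE(cfg$simulate)) {
      sc <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                  as.list(cfg$sim)))
      bundle <<- simulate_cohort(sc)
      export_fixture(bundle, p("inputs"))
    } else {
      bundle <<- read_fixture(cfg$input_dir)
    }
    list(n_mirnas = nrow(bundle$mirna_counts$values),
         n_genes = nrow(bundle$gene_counts$values),
         n_snvs = nrow(bundle$genotypes$dosages),
         n_samples = ncol(bundle$mirna_counts$values),
         simulated = isTRUE(cfg$simulate))
  })
  input_dir <- if (isTRUE(cfg$simulate)) p("inputs") else cfg$input_dir
  manifest$input_checksums <- as.list(tools::md5sum(
    list.files(input_dir, full.names = TRUE)))

  ## preprocess ---------------------------------------------------------
  filt <- norm_mirna <- norm_gene <- sf <- NULL
  stage("preprocess", function() {
    filt <<- filter_by_median(bundle$mirna_counts, cfg$median_threshold)
    sf <<- size_factors(filt$counts)
    norm_mirna <<- normalize_counts(filt$counts, sf)
    gene_filt <- filter_by_median(bundle$gene_counts, cfg$median_threshold)
    sf_g <- size_factors(gene_filt$counts)
    norm_gene <<- normalize_counts(gene_filt$counts, sf_g)
    write_counts(norm_mirna, p("mirna_normalized.tsv"))
    write_counts(cpm(filt$counts), p("mirna_cpm.tsv"))
    write_counts(norm_gene, p("gene_normalized.tsv"))
    list(mirnas_kept = length(filt$kept), mirnas_dropped = length(filt$dropped),
         genes_kept = nrow(norm_gene$values))
  })

  ## differential expression -------------------------------------------
  de <- list()
  stage("de", function() {
    groups <- bundle$samples$group[match(colnames(filt$counts$values),
                                         bundle$samples$sample_id)]
    disp <- estimate_dispersion(filt$counts, groups, sf)
    contrasts <- list(t1_vs_t2 = c("T1", "T2"),
                      t2_vs_term = c("T2", "NORM"),
                      norm_vs_pe = c("NORM", "PE"))
    for (nm in names(contrasts)) {
      res <- nb_wald_test(filt$counts, bundle$samples, contrasts[[nm]],
                          covariates = cfg$de_covariates, sf = sf, disp = disp)
      res$direction <- classify_direction(res, cfg$alpha)
      de[[nm]] <<- res
      write_results(res, p(paste0("de_", nm, ".tsv")))
    }
    vapply(de, function(r) sum(!is.na(r$fdr) & r$fdr < cfg$alpha), 0L)
  })

  ## dynamics -----------------------------------------------------------
  patterns <- NULL
  stage("dynamics", function() {
    patterns <<- assign_pattern(de$t1_vs_t2, de$t2_vs_term, cfg$alpha)
    smry <- summarize_patterns(patterns, bundle$annotation)
    utils::write.table(
      data.frame(pattern = rownames(smry$counts), smry$counts,
                 check.names = FALSE),
      p("dynamics_summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(patterns, p("dynamics_patterns.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(n_classified = nrow(patterns),
         n_dynamic = sum(patterns$pattern != "NoChange-NoChange"))
  })

  ## correlation landscape ----------------------------------------------
  corr <- clustering <- gene_lists <- NULL
  stage("correlate", function() {
    term_ids <- bundle$samples$sample_id[bundle$samples$trimester == "term"]
    pe_de <- de$norm_vs_pe
    sel <- pe_de$feature_id[!is.na(pe_de$fdr) & pe_de$fdr < cfg$alpha]
    if (length(sel) < cfg$k_groups) sel <- pe_de$feature_id  # fall back to all tested
    mir_term <- subset_counts(norm_mirna, features = sel,
                              samples = intersect(term_ids,
                                                  colnames(norm_mirna$values)))
    gene_term <- subset_counts(norm_gene,
                               samples = intersect(term_ids,
                                                   colnames(norm_gene$values)))
    corr <<- pairwise_spearman(mir_term, gene_term)
    k <- min(cfg$k_groups, nrow(corr$rho))
    clustering <<- cluster_mirnas(corr, k = k)
    write_dendrogram_newick(clustering, p("mirna_dendrogram.nwk"))
    utils::write.table(
      data.frame(mirna_id = names(clustering$groups),
                 group = unname(clustering$groups)),
      p("mirna_groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    rho_out <- data.frame(mirna_id = rownames(corr$rho),
                          signif(corr$rho, 6), check.names = FALSE)
    utils::write.table(rho_out, p("correlation_rho.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gene_lists <<- list()
    for (g in sort(unique(clustering$groups))) {
      members <- names(clustering$groups)[clustering$groups == g]
      for (dir in c("negative", "positive")) {
        gene_lists[[paste(g, dir, sep = "_")]] <<- correlated_gene_lists(
          corr, members, dir,
          median_threshold = cfg$median_rho_threshold,
          individual_threshold = cfg$individual_rho_threshold)
      }
    }
    writeLines(
      vapply(names(gene_lists), function(nm) {
        paste(c(nm, gene_lists[[nm]]), collapse = "\t")
      }, ""),
      p("correlated_gene_lists.tsv"))
    list(n_pairs = length(corr$rho), n_mirnas = nrow(corr$rho),
         k = clustering$k,
         list_sizes = lengths(gene_lists))
  })

  ## enrichment ----------------------------------------------------------
  stage("enrich", function() {
    background <- colnames(corr$rho)
    rows <- list()
    for (nm in names(gene_lists)) {
      q <- gene_lists[[nm]]
      if (!length(q)) next
      e <- hypergeometric_enrichment(q, bundle$gene_sets, background)
      if (nrow(e)) { e$query_list <- nm; rows[[nm]] <- e }
    }
    enr <- if (length(rows)) do.call(rbind, rows) else
      data.frame(set_id = character(), p_value = numeric(), fdr = numeric())
    write_results(enr, p("enrichment.tsv"))
    list(n_tests = nrow(enr),
         n_significant = sum(!is.na(enr$fdr) & enr$fdr < cfg$alpha))
  })

  ## eQTL scan ------------------------------------------------------------
  eqtl <- NULL
  stage("eqtl", function() {
    mf <- maf_hwe_filter(bundle$genotypes, maf_min = cfg$maf_min)
    utils::write.table(mf$report, p("snv_filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    annot <- bundle$annotation[bundle$annotation$feature_id %in%
                                 rownames(norm_mirna$values), , drop = FALSE]
    pairs <- enumerate_pairs(mf$genotypes, annot, flank = cfg$flank)
    term_meta <- bundle$samples[bundle$samples$trimester == "term", ]
    eqtl <<- eqtl_scan(norm_mirna, mf$genotypes, term_meta, pairs)
    write_results(eqtl, p("eqtl_results.tsv"))
    list(n_snvs_kept = nrow(mf$genotypes$dosages), n_pairs = nrow(pairs),
         n_tests = nrow(eqtl),
         n_significant = sum(eqtl$fdr < cfg$alpha))
  })

  ## trait association -----------------------------------------------------
  assoc <- top_snvs <- NULL
  traits <- c(TRAIT_NAMES, "pe_diagnosis", "gd_diagnosis")
  stage("associate", function() {
    top_snvs <<- utils::head(unique(eqtl$snv_id[order(eqtl$fdr)]), 3L)
    if (!length(top_snvs)) stop("no eQTL results to carry forward")
    term_meta <- bundle$samples[bundle$samples$trimester == "term", ]
    traits <- intersect(traits, names(term_meta))
    g <- bundle$genotypes
    gsub_ <- new_genotypes(
      g$dosages[top_snvs, , drop = FALSE],
      g$info[match(top_snvs, g$info$snv_id), , drop = FALSE])
    assoc <<- trait_association(term_meta, gsub_, traits)
    write_results(assoc, p("trait_association.tsv"))
    list(n_snvs = length(top_snvs), n_tests = nrow(assoc),
         n_significant = sum(assoc$fdr < cfg$alpha))
  })

  ## meta-analysis ----------------------------------------------------------
  stage("meta", function() {
    term_meta <- bundle$samples[bundle$samples$trimester == "term", ]
    traits <- intersect(traits, names(term_meta))
    # alternate in pairs so each pseudo-cohort keeps both sexes (samples
    # alternate XX/XY) and a share of every clinical group (blocks of 8)
    halves <- split(term_meta,
                    rep(rep(c("cohortA", "cohortB"), each = 2),
                        length.out = nrow(term_meta)))
    g <- bundle$genotypes
    gsub_ <- new_genotypes(
      g$dosages[top_snvs, , drop = FALSE],
      g$info[match(top_snvs, g$info$snv_id), , drop = FALSE])
    cohort_res <- lapply(halves, function(h) {
      trait_association(h, gsub_, traits, min_n = 8L)
    })
    meta_res <- meta_across_cohorts(cohort_res)
    write_results(meta_res, p("meta_results.tsv"))
    list(n_pooled = nrow(meta_res),
         n_significant = sum(meta_res$fdr < cfg$alpha))
  })

  manifest$config <- cfg[setdiff(names(cfg), "sim")]
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed N --out DIR` and
#' `run-all --config FILE.json --out DIR [--seed N]`. Used by the
#' `inst/cli/placentamir.R` script.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status 0 invisibly; errors propagate.
#' @export
pmir_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: placentamir <simulate|run-all>",
                 "[--config FILE] [--seed N] --out DIR")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- list(seed = NULL, config = NULL, out = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) stop(usage, call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$out)) stop(usage, call. = FALSE)
  if (cmd == "simulate") {
    seed <- as.integer(if (is.null(opt$seed)) 1L else opt$seed)
    bundle <- simulate_cohort(sim_config(seed = seed))
    export_fixture(bundle, opt$out)
    message("fixture written to ", opt$out)
  } else if (cmd == "run-all") {
    cfg <- if (is.null(opt$config)) list() else pipeline_config(opt$config)
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    run_pipeline(cfg, opt$out)
    message("pipeline complete; manifest at ",
            file.path(opt$out, "manifest.json"))
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
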