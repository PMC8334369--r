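# Readers and writers for every external artifact the pipeline touches.
# Internal coordinate convention is 0-based half-open everywhere; BED is
# native, GFF3 and VCF positions are converted at the boundary. Malformed
# input is rejected with the offending line/id named — never silently
# repaired (sole documented exception: multi-allelic VCF records are
# skipped with a warning).

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged TSV '", path, "': line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a feature x sample count table
#'
#' TSV with the feature id in the first column and a header row of sample
#' ids. Raw matrices must contain nonnegative integers.
#'
#' @param path TSV file path.
#' @param kind expected matrix kind ("raw", "normalized" or "cpm").
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, kind = "raw") {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop("read_counts: no sample columns in ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("read_counts: duplicated feature id '", dup[1], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("read_counts: non-numeric values in ", path)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("read_counts: missing value at line ", bad + 1L)
  }
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)[1]
    stop("read_counts: negative value at line ", bad + 1L)
  }
  if (kind == "raw" && any(m != round(m))) {
    bad <- which(rowSums(m != round(m)) > 0)[1]
    stop("read_counts: non-integer raw count at line ", bad + 1L)
  }
  rownames(m) <- ids
  count_matrix(m, kind)
}

#' Write a count matrix as TSV
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- cm$values
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (cm$kind != "raw") {
    for (j in seq(2, ncol(df))) df[[j]] <- signif(df[[j]], 10)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SAMPLE_GROUPS <- c("NORM", "PE", "GD", "SGA", "LGA", "T1", "T2")
TRIMESTERS <- c("1", "2", "term")

#' Read and validate the sample metadata table
#'
#' Required columns: `sample_id`, `trimester` (1/2/term),
#' `gestational_days` (30-320), `fetal_sex` (XX/XY), `group`
#' (NORM/PE/GD/SGA/LGA/T1/T2). Any further columns are treated as traits.
#' Group and trimester must be consistent (T1/T2 groups in trimesters 1/2,
#' clinical groups at term).
#'
#' @param path TSV path.
#' @return data.frame with validated columns.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_checked(path)
  validate_sample_table(df)
}

validate_sample_table <- function(df) {
  need <- c("sample_id", "trimester", "gestational_days", "fetal_sex", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sample table: missing column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$trimester <- as.character(df$trimester)
  if (anyDuplicated(df$sample_id)) {
    stop("sample table: duplicate sample_id '",
         df$sample_id[duplicated(df$sample_id)][1], "'")
  }
  if (!all(df$trimester %in% TRIMESTERS)) {
    stop("sample table: trimester must be one of ",
         paste(TRIMESTERS, collapse = "/"))
  }
  if (any(df$gestational_days < 30 | df$gestational_days > 320)) {
    stop("sample table: gestational_days outside [30, 320]")
  }
  if (!all(df$fetal_sex %in% c("XX", "XY"))) {
    stop("sample table: fetal_sex must be XX or XY")
  }
  if (!all(df$group %in% SAMPLE_GROUPS)) {
    stop("sample table: unknown group value(s): ",
         paste(setdiff(df$group, SAMPLE_GROUPS), collapse = ", "))
  }
  bad <- (df$group == "T1" & df$trimester != "1") |
    (df$group == "T2" & df$trimester != "2") |
    (!df$group %in% c("T1", "T2") & df$trimester != "term")
  if (any(bad)) {
    stop("sample table: group/trimester inconsistent for sample(s): ",
         paste(utils::head(df$sample_id[bad], 5), collapse = ", "))
  }
  df
}

#' Write the sample metadata table
#' @param meta validated sample data.frame.
#' @param path output path.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CLUSTER_LEVELS <- c("C19MC", "C14MC", "miR371_373", "other")

new_annotation <- function(df) {
  stopifnot(all(c("feature_id", "chrom", "start", "end", "strand", "cluster")
                %in% names(df)))
  if (anyDuplicated(df$feature_id)) {
    stop("annotation: duplicate feature id '",
         df$feature_id[duplicated(df$feature_id)][1], "'")
  }
  if (any(df$start >= df$end)) {
    bad <- df$feature_id[df$start >= df$end][1]
    stop("annotation: start >= end for feature '", bad, "'")
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("annotation: strand must be one of + - .")
  }
  df$cluster[is.na(df$cluster) | df$cluster == ""] <- "other"
  if (!all(df$cluster %in% CLUSTER_LEVELS)) {
    stop("annotation: unknown cluster label(s): ",
         paste(setdiff(df$cluster, CLUSTER_LEVELS), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read a genomic feature annotation (BED or GFF3)
#'
#' BED is 0-based half-open and used natively; an optional 7th column
#' carries the cluster label (C19MC / C14MC / miR371_373 / other). GFF3 is
#' 1-based inclusive and converted on read (start - 1); the feature id is
#' taken from the `ID` or `Name` attribute and the cluster from a `cluster`
#' attribute when present.
#'
#' @param path file path.
#' @param format "bed" or "gff3".
#' @return data.frame: feature_id, chrom, start, end (0-based half-open),
#'   strand, cluster.
#' @export
read_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (format == "bed") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 6L)) {
      stop("read_annotation: BED line ", which(nf < 6L)[1],
           " has fewer than 6 fields")
    }
    df <- data.frame(
      feature_id = vapply(parts, `[`, "", 4L),
      chrom = vapply(parts, `[`, "", 1L),
      start = as.integer(vapply(parts, `[`, "", 2L)),
      end = as.integer(vapply(parts, `[`, "", 3L)),
      strand = vapply(parts, `[`, "", 6L),
      cluster = vapply(parts, function(p) if (length(p) >= 7L) p[7L] else "other", ""),
      stringsAsFactors = FALSE
    )
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 9L)) {
      stop("read_annotation: GFF3 line ", which(nf != 9L)[1],
           " does not have 9 fields")
    }
    attr_field <- vapply(parts, `[`, "", 9L)
    get_attr <- function(att, key) {
      m <- regmatches(att, regexec(paste0("(?:^|;)", key, "=([^;]+)"), att))
      vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
    }
    id <- get_attr(attr_field, "ID")
    nm <- get_attr(attr_field, "Name")
    id[is.na(id)] <- nm[is.na(id)]
    if (anyNA(id)) {
      stop("read_annotation: GFF3 record without ID or Name attribute at line ",
           which(is.na(id))[1])
    }
    df <- data.frame(
      feature_id = id,
      chrom = vapply(parts, `[`, "", 1L),
      start = as.integer(vapply(parts, `[`, "", 4L)) - 1L,  # to 0-based
      end = as.integer(vapply(parts, `[`, "", 5L)),
      strand = vapply(parts, `[`, "", 7L),
      cluster = get_attr(attr_field, "cluster"),
      stringsAsFactors = FALSE
    )
    df$cluster[is.na(df$cluster)] <- "other"
  }
  new_annotation(df)
}

#' Write an annotation as BED6+1
#' @param annot annotation data.frame (internal 0-based half-open).
#' @param path output path.
#' @export
write_annotation_bed <- function(annot, path) {
  bed <- data.frame(annot$chrom, annot$start, annot$end, annot$feature_id,
                    ".", annot$strand, annot$cluster)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

new_genotypes <- function(dosages, info) {
  stopifnot(is.matrix(dosages),
            all(c("snv_id", "chrom", "pos", "ref", "alt") %in% names(info)),
            nrow(info) == nrow(dosages))
  if (anyDuplicated(info$snv_id)) {
    stop("genotypes: duplicate snv_id '",
         info$snv_id[duplicated(info$snv_id)][1], "'")
  }
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("genotypes: dosages must be 0/1/2 or missing")
  rownames(dosages) <- info$snv_id
  rownames(info) <- NULL
  structure(list(dosages = dosages, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNVs x %d samples (minor-allele dosages)\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

recode_to_minor <- function(dosages, info) {
  # dosage currently counts ALT; flip any SNV whose alt frequency > 0.5 in
  # the loaded cohort so that dosage counts the cohort minor allele
  f_alt <- rowMeans(dosages, na.rm = TRUE) / 2
  flip <- !is.na(f_alt) & f_alt > 0.5
  dosages[flip, ] <- 2 - dosages[flip, , drop = FALSE]
  info$minor_is_ref <- flip
  list(dosages = dosages, info = info)
}

#' Read genotypes from a minimal VCF
#'
#' Parses GT from a VCF 4.x text file. Only biallelic records are kept;
#' multi-allelic records are skipped with a warning. `./.` becomes missing.
#' ALT-allele counts are re-coded so that the stored dosage counts the
#' MINOR allele of the loaded cohort; the original ref/alt orientation is
#' preserved in the `info` table (`minor_is_ref`).
#'
#' @param path VCF path (uncompressed text).
#' @return a `genotype_matrix` (positions converted to 0-based).
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("read_genotypes_vcf: missing #CHROM header line")
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L) stop("read_genotypes_vcf: no sample columns")
  samples <- header[-(1:9)]
  body <- lines[seq(hdr + 1L, length(lines))]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  keep <- logical(length(rows))
  dos <- matrix(NA_real_, nrow = length(rows), ncol = length(samples))
  info <- data.frame(snv_id = character(length(rows)), chrom = "",
                     pos = 0L, ref = "", alt = "", stringsAsFactors = FALSE)
  n_multi <- 0L
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(header)) {
      stop("read_genotypes_vcf: line ", hdr + i, " has ", length(r),
           " fields, expected ", length(header))
    }
    if (grepl(",", r[5], fixed = TRUE)) { n_multi <- n_multi + 1L; next }
    fmt <- strsplit(r[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) {
      stop("read_genotypes_vcf: record at line ", hdr + i,
           " has no GT in FORMAT")
    }
    gt <- vapply(strsplit(r[-(1:9)], ":", fixed = TRUE), `[`, "", gt_idx)
    alleles <- strsplit(gt, "[/|]")
    dos[i, ] <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, 0)
    info$snv_id[i] <- if (r[3] == ".") paste0(r[1], ":", r[2]) else r[3]
    info$chrom[i] <- r[1]
    info$pos[i] <- as.integer(r[2]) - 1L  # to 0-based
    info$ref[i] <- r[4]; info$alt[i] <- r[5]
    keep[i] <- TRUE
  }
  if (n_multi > 0L) {
    warning("read_genotypes_vcf: skipped ", n_multi, " multi-allelic record(s)")
  }
  if (!any(keep)) stop("read_genotypes_vcf: no usable biallelic records")
  rc <- recode_to_minor(dos[keep, , drop = FALSE], info[keep, , drop = FALSE])
  colnames(rc$dosages) <- samples
  new_genotypes(rc$dosages, rc$info)
}

#' Write a genotype matrix as minimal VCF
#'
#' Inverse of [read_genotypes_vcf()] up to phasing: dosages are written as
#' unphased GT in the original ref/alt orientation (minor-allele recoding
#' is undone using `minor_is_ref`).
#'
#' @param geno a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  info <- geno$info
  dos <- geno$dosages
  if (!is.null(info$minor_is_ref)) {
    flip <- info$minor_is_ref
    dos[flip, ] <- 2 - dos[flip, , drop = FALSE]
  }
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dos)), collapse = "\t")), con)
  for (i in seq_len(nrow(dos))) {
    writeLines(paste(c(info$chrom[i], info$pos[i] + 1L, info$snv_id[i],
                       info$ref[i], info$alt[i], ".", "PASS", ".", "GT",
                       gt_of(dos[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a miRNA -> target gene map
#'
#' TSV with columns `mirna_id`, `gene_id` and optional `evidence`
#' (high/other). Rows with empty gene ids are rejected.
#'
#' @param path TSV path.
#' @return data.frame(mirna_id, gene_id, evidence).
#' @export
read_target_map <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("mirna_id", "gene_id")
  if (!all(need %in% names(df))) {
    stop("read_target_map: required columns mirna_id, gene_id")
  }
  if (any(!nzchar(df$gene_id))) stop("read_target_map: empty gene_id")
  if (is.null(df$evidence)) df$evidence <- "high"
  if (!all(df$evidence %in% c("high", "other"))) {
    stop("read_target_map: evidence must be 'high' or 'other'")
  }
  df[, c("mirna_id", "gene_id", "evidence")]
}

#' Targets of one miRNA
#' @param target_map data.frame from [read_target_map()].
#' @param mirna_id miRNA identifier.
#' @param evidence evidence levels to keep.
#' @return character vector of gene ids (possibly empty).
#' @export
targets_of <- function(target_map, mirna_id, evidence = "high") {
  unique(target_map$gene_id[target_map$mirna_id == mirna_id &
                              target_map$evidence %in% evidence])
}

#' Read gene sets in GMT format
#'
#' @param path GMT path: set id, description, then member genes, tab-separated.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop("read_gmt: line ", short[1], " has fewer than 3 fields")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop("read_gmt: duplicate set id '", names(sets)[duplicated(names(sets))][1], "'")
  }
  sets
}

#' Write a result table as deterministic TSV
#'
#' Stable column order as given; numeric columns rounded to 6 significant
#' digits; rows ordered by `fdr` then the first id-like column when
#' present, so that identical inputs give byte-identical files.
#'
#' @param table data.frame of results.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  df <- as.data.frame(table)
  if (nrow(df) > 0 && "fdr" %in% names(df)) {
    idcol <- intersect(c("feature_id", "mirna_id", "snv_id", "set_id", "gene_id"),
                       names(df))
    key <- if (length(idcol)) df[[idcol[1]]] else seq_len(nrow(df))
    df <- df[order(df$fdr, key), , drop = FALSE]
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
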