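# All tables leave the package as TSV with a schema declaration in a leading
# comment line; readers validate the schema before parsing. Coordinates are
# 1-based (VCF convention) throughout.

schema_line <- function(df) paste0("#partprs_schema: ",
                                   paste(names(df), collapse = ","))

#' Write / read a schema-tagged TSV
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return `read_tsv_schema` returns the data.frame; writers return the path
#'   invisibly.
#' @export
write_tsv_schema <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(schema_line(df), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_schema
#' @param expected_cols optional character vector the schema must equal.
#' @export
read_tsv_schema <- function(path, expected_cols = NULL) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#partprs_schema: "))
    stop("missing schema header in ", path)
  declared <- strsplit(sub("^#partprs_schema: ", "", first), ",")[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), declared))
    stop("schema mismatch in ", path, ": declared ",
         paste(declared, collapse = ","), " but found ",
         paste(names(df), collapse = ","))
  if (!is.null(expected_cols) && !identical(declared, expected_cols))
    stop("unexpected schema in ", path)
  df
}

#' Write a genotype matrix
#'
#' TSV layout: one row per variant with metadata columns (`variant_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`) followed by one
#' dosage column per sample (4 decimals; `NA` for missing). VCF layout:
#' VCFv4.2 with a `DS` FORMAT field, ALT = effect allele (dosages count ALT
#' copies), missing dosage written as `.`.
#'
#' @param gm genotype_matrix.
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  format <- match.arg(format)
  v <- gm$variants
  if (format == "tsv") {
    D <- t(gm$dosages)
    df <- data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                     effect_allele = v$effect_allele,
                     other_allele = v$other_allele,
                     eaf = round(v$eaf, 6), stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(round(D, 4)))
    write_tsv_schema(df, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", gm$sample_ids),
                       collapse = "\t")), con)
    D <- round(t(gm$dosages), 4)
    ds <- matrix(sprintf("%.4f", D), nrow = nrow(D))
    ds[is.na(D)] <- "."
    lines <- paste(v$chrom, v$pos, v$variant_id, v$other_allele,
                   v$effect_allele, ".", ".", ".", "DS",
                   apply(ds, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a genotype matrix
#'
#' @param path TSV written by [write_genotypes()] or a VCF with a `DS`
#'   dosage field (parsed with VariantAnnotation).
#' @param format `"tsv"` or `"vcf"`.
#' @return genotype_matrix. Dosages round-trip to 4 decimals; a missing DS
#'   entry becomes a missing dosage (never 0).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_schema(path)
    meta_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf")
    miss <- setdiff(meta_cols, names(df))
    if (length(miss)) stop("genotype TSV lacks columns: ",
                           paste(miss, collapse = ", "))
    if (anyDuplicated(df$variant_id))
      stop("duplicated variant ids in ", path)
    samp <- setdiff(names(df), meta_cols)
    D <- t(as.matrix(df[, samp, drop = FALSE]))
    dimnames(D) <- list(samp, df$variant_id)
    v <- df[, meta_cols]
    v$chrom <- as.character(v$chrom)
    genotype_matrix(D, v)
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("VariantAnnotation is required to read VCF")
    vcf <- VariantAnnotation::readVcf(path)
    ds <- VariantAnnotation::geno(vcf)$DS
    if (is.null(ds)) stop("VCF has no DS (dosage) FORMAT field: ", path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ids <- names(rr)
    if (anyDuplicated(ids)) stop("duplicated variant ids in ", path)
    alt <- as.character(unlist(rr$ALT))
    v <- data.frame(variant_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = BiocGenerics::start(rr),
                    effect_allele = alt,
                    other_allele = as.character(rr$REF),
                    stringsAsFactors = FALSE)
    D <- t(matrix(as.numeric(ds), nrow = nrow(ds),
                  dimnames = dimnames(ds)))
    genotype_matrix(D, v)
  }
}

#' Write / read a phenotype table
#' @param phenotypes data.frame keyed by `sample_id`.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot("sample_id" %in% names(phenotypes))
  write_tsv_schema(phenotypes, path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_schema(path)
  if (!"sample_id" %in% names(df)) stop("phenotype table lacks sample_id")
  df
}

#' Serialize / restore a simulation configuration as JSON
#'
#' Round-trips a [sim_config()] losslessly (numeric exactness via full
#' double precision).
#'
#' @param config sim_config.
#' @param path JSON file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$discordant_loci <- lapply(x$discordant_loci, unclass)
  x$concordant_loci <- lapply(x$concordant_loci, unclass)
  # named atomic vectors would lose their names as JSON arrays
  x$adiposity_mean <- as.list(x$adiposity_mean)
  x$adiposity_sd <- as.list(x$adiposity_sd)
  # I(17) significant digits: exact IEEE double round-trip
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_pv <- function(p) planted_variant(p$variant_id, p$maf, p$beta_pdff,
                                       p$beta_tg, p$n_tags, p$tag_r2)
  loci <- function(l) {
    if (is.data.frame(l)) l <- split(l, seq_len(nrow(l)))
    lapply(l, mk_pv)
  }
  R <- as.matrix(x$adiposity_corr)
  dimnames(R) <- list(names(x$adiposity_mean), names(x$adiposity_mean))
  sim_config(n_samples = x$n_samples,
             n_null_variants = x$n_null_variants,
             discordant_loci = unname(loci(x$discordant_loci)),
             concordant_loci = unname(loci(x$concordant_loci)),
             adiposity_mean = unlist(x$adiposity_mean),
             adiposity_sd = unlist(x$adiposity_sd),
             adiposity_corr = R,
             mediation_fraction = x$mediation_fraction,
             mediated_index = x$mediated_index,
             outcome_spec = as.data.frame(x$outcome_spec),
             noise_sd = x$noise_sd,
             interaction_coef = x$interaction_coef,
             follow_up_years = x$follow_up_years,
             seed = x$seed)
}
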