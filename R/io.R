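# Readers and writers for the interchange formats: VCF genotypes,
# local-ancestry segment TSV, IBD match TSV, and the pipeline configuration.
# Coordinates are 0-based half-open internally; VCF positions are converted
# at the boundary. Genetic positions serialize with 4 decimals.

#' Write genotypes as a minimal VCF
#'
#' Biallelic SNVs with a GT field; phased haplotypes are written when the
#' table carries them, otherwise unphased genotypes. Physical positions are
#' derived from genetic positions at 1 cM/Mb.
#'
#' @param table an [ancestry_genotype_table()].
#' @param path output path.
#' @param sample_names optional individual names.
#' @export
write_genotypes <- function(table, path, sample_names = NULL) {
  n_ind <- ncol(table$G)
  if (is.null(sample_names)) sample_names <- sprintf("ind%03d", seq_len(n_ind))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(table$sites$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  pos_bp <- as.integer(round(table$sites$pos_cM * 1e4)) + 1L
  gt <- if (!is.null(table$H1)) {
    m <- matrix(paste0(table$H1, "|", table$H2), nrow = nrow(table$G))
    m[is.na(table$H1) | is.na(table$H2)] <- ".|."
    m
  } else {
    m <- matrix("", nrow(table$G), n_ind)
    m[table$G == 0] <- "0/0"; m[table$G == 1] <- "0/1"; m[table$G == 2] <- "1/1"
    m[is.na(table$G)] <- "./."
    m
  }
  body <- paste(table$sites$chrom, pos_bp,
                paste0("site", table$sites$id), "A", "T", ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses the GT field of biallelic SNVs through Bioconductor's
#' VariantAnnotation; multiallelic records are skipped with a message.
#'
#' @param path VCF path.
#' @return an [ancestry_genotype_table()] (genotype part only; ancestry
#'   matrices are `NA`), with genetic positions back-converted at 1 cM/Mb.
#' @export
read_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_genotypes requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt_n <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  multi <- alt_n > 1L
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped")
  vcf <- vcf[!multi]
  gt <- VariantAnnotation::geno(vcf)$GT
  n_s <- nrow(gt)
  parse_gt <- function(g) {
    a <- matrix(NA_integer_, nrow(g), ncol(g))
    a[g %in% c("0|0", "0/0")] <- 0L
    a[g %in% c("0|1", "1|0", "0/1", "1/0")] <- 1L
    a[g %in% c("1|1", "1/1")] <- 2L
    a
  }
  G <- parse_gt(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos_cM = (GenomicRanges::start(rr) - 1L) / 1e4,
    id = seq_len(n_s), stringsAsFactors = FALSE)
  first <- substr(gt, 1L, 1L); second <- substr(gt, 3L, 3L)
  phased <- all(substr(gt, 2L, 2L) == "|")
  H1 <- H2 <- NULL
  if (phased && n_s > 0) {
    H1 <- matrix(as.integer(first), n_s); H2 <- matrix(as.integer(second), n_s)
  }
  na_m <- matrix(NA_character_, n_s, ncol(G))
  ancestry_genotype_table(sites, G, na_m, na_m, H1, H2)
}

#' Write local-ancestry segments as TSV
#'
#' Columns: chrom, start, end (cM, 0-based half-open, 4 decimals),
#' individual, hap index, ancestry label.
#'
#' @param tracts a `tract_set`.
#' @param path output path.
#' @export
write_local_ancestry <- function(tracts, path) {
  df <- data.frame(chrom = tracts$chrom,
                   start = sprintf("%.4f", tracts$start_cM),
                   end = sprintf("%.4f", tracts$end_cM),
                   individual = tracts$ind, hap = tracts$hap,
                   ancestry = tracts$ancestry)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read local-ancestry segments from TSV
#'
#' @param path TSV path (see [write_local_ancestry()] for the dialect).
#' @param genome the [genome_map()] the segments live on.
#' @return a `tract_set`; per-haplotype tiling is validated and any overlap
#'   or gap is an error reporting the offending locus.
#' @export
read_local_ancestry <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "individual", "hap", "ancestry")
  if (!all(need %in% names(df))) stop("missing local-ancestry columns")
  out <- data.frame(ind = df$individual, hap = df$hap, chrom = df$chrom,
                    start_cM = as.numeric(df$start), end_cM = as.numeric(df$end),
                    ancestry = df$ancestry, stringsAsFactors = FALSE)
  tryCatch(tract_set(out, genome),
           error = function(e) stop("invalid ancestry tiling: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write IBD segments as a match-style TSV
#'
#' Columns: id1, hap1, id2, hap2, chrom, start, end (cM), length_cM.
#'
#' @param segments an `ibd_set`.
#' @param path output path.
#' @export
write_ibd <- function(segments, path) {
  df <- data.frame(id1 = segments$id1, hap1 = segments$hap1,
                   id2 = segments$id2, hap2 = segments$hap2,
                   chrom = segments$chrom,
                   start = sprintf("%.4f", segments$start_cM),
                   end = sprintf("%.4f", segments$end_cM),
                   length_cM = sprintf("%.4f", segments$length_cM))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read IBD segments from a match-style TSV
#'
#' @param path TSV path.
#' @param populations optional named vector mapping individual id to
#'   population label; when given, segments are classified as
#'   `"within"`/`"across"`.
#' @return an `ibd_set`.
#' @export
read_ibd <- function(path, populations = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id1", "hap1", "id2", "hap2", "chrom", "start", "end", "length_cM")
  if (!all(need %in% names(df))) stop("missing IBD columns")
  out <- data.frame(id1 = df$id1, hap1 = df$hap1, id2 = df$id2, hap2 = df$hap2,
                    chrom = df$chrom, start_cM = as.numeric(df$start),
                    end_cM = as.numeric(df$end),
                    length_cM = as.numeric(df$length_cM),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    out <- data.frame(id1 = integer(), hap1 = integer(), id2 = integer(),
                      hap2 = integer(), chrom = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      length_cM = numeric(), stringsAsFactors = FALSE)
  if (any(out$length_cM <= 0)) stop("non-positive IBD segment length")
  if (!is.null(populations) && nrow(out)) {
    p1 <- populations[as.character(out$id1)]
    p2 <- populations[as.character(out$id2)]
    out$group <- ifelse(p1 == p2, "within", "across")
  }
  ibd_set(out)
}

#' Pipeline configuration
#'
#' A validated list of per-stage parameter blocks with explicit seeds (no
#' hidden entropy), serialized as JSON.
#'
#' @param stages named list of per-stage parameter lists; each stage must
#'   carry a `seed`.
#' @param out_dir output directory recorded in the configuration.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages, out_dir = ".") {
  if (is.null(names(stages)) || any(names(stages) == ""))
    stop("stages must be named")
  for (nm in names(stages))
    if (is.null(stages[[nm]]$seed))
      stop("stage '", nm, "' has no explicit seed")
  structure(list(stages = stages, out_dir = out_dir),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> stages:", paste(names(x$stages), collapse = ", "),
      "\n  out_dir:", x$out_dir, "\n")
  invisible(x)
}

#' Read / write pipeline configuration (JSON)
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(x$stages, x$out_dir)
}
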