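#' Genetic map of a genome
#'
#' A genome map lists the chromosomes and their genetic lengths in Morgans.
#' All tract and IBD computations in this package work in genetic units; an
#' optional physical length per chromosome is carried along only for writers
#' that need base-pair coordinates (VCF output).
#'
#' @param lengths numeric vector of chromosome genetic lengths in Morgans,
#'   strictly positive.
#' @param names optional chromosome names; defaults to `"chr1"`, `"chr2"`, ...
#' @param bp optional physical lengths in base pairs (one per chromosome).
#' @return an object of class `genome_map`: a data.frame with columns
#'   `chrom`, `length_M` and optionally `length_bp`, with attribute
#'   `total_M` giving the summed genetic length.
#' @examples
#' g <- genome_map(c(2.8, 2.5, 2.2))
#' sum(g$length_M)
#' @export
genome_map <- function(lengths, names = NULL, bp = NULL) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be strictly positive and finite")
  if (is.null(names)) names <- paste0("chr", seq_along(lengths))
  if (anyDuplicated(names)) stop("duplicate chromosome names")
  g <- data.frame(chrom = as.character(names), length_M = lengths,
                  stringsAsFactors = FALSE)
  if (!is.null(bp)) {
    if (length(bp) != length(lengths) || any(bp <= 0))
      stop("bp lengths must match chromosomes and be positive")
    g$length_bp <- as.numeric(bp)
  } else {
    # 1 cM/Mb convention keeps physical coordinates well-defined for writers
    g$length_bp <- round(lengths * 1e8)
  }
  attr(g, "total_M") <- sum(lengths)
  class(g) <- c("genome_map", "data.frame")
  g
}

#' Default human-autosome-scale genome map
#'
#' Twenty-two chromosomes with relative genetic lengths proportional to the
#' human autosomes, rescaled so the total genome length is exactly
#' `total_M` Morgans (default 35, the scale of the human autosomal map).
#'
#' @param total_M total genome genetic length in Morgans.
#' @return a [genome_map()].
#' @export
default_genome <- function(total_M = 35) {
  rel <- c(2.78, 2.52, 2.23, 2.14, 2.04, 1.92, 1.87, 1.68, 1.66, 1.81,
           1.58, 1.74, 1.26, 1.19, 1.41, 1.34, 1.28, 1.17, 1.07, 1.08,
           0.62, 0.72)
  genome_map(rel * total_M / sum(rel))
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %d chromosomes, %.3f Morgans total\n",
              nrow(x), attr(x, "total_M")))
  invisible(x)
}

total_morgans <- function(genome) attr(genome, "total_M")
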