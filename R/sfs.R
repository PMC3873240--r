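# Joint site frequency spectra: container, hypergeometric projection,
# masking, and the plain-text serialization format.

#' Construct a joint site frequency spectrum
#'
#' @param counts numeric vector/matrix/array of derived-allele class counts;
#'   dimension `d` gives a spectrum over `d` populations, with extent
#'   `n_i + 1` along axis `i` for sample size `n_i` haploids.
#' @param pops population names (default `pop1`, ...).
#' @param mask logical array of the same shape; `TRUE` entries are excluded
#'   from likelihoods. Default masks the two fixed corners (all-ancestral,
#'   all-derived).
#' @param folded logical; spectra here are unfolded (derived counts).
#' @return object of class `joint_sfs`.
#' @export
joint_sfs <- function(counts, pops = NULL, mask = NULL, folded = FALSE) {
  a <- as.array(counts)
  if (any(a < 0)) stop("SFS entries must be non-negative")
  nd <- length(dim(a))
  if (is.null(pops)) pops <- paste0("pop", seq_len(nd))
  if (length(pops) != nd) stop("one population name per dimension")
  if (is.null(mask)) {
    mask <- array(FALSE, dim(a))
    corner <- function(k) matrix(k, 1, nd)
    mask[corner(1L)] <- TRUE                    # all-ancestral cell
    mask[matrix(dim(a), 1, nd)] <- TRUE         # all-derived cell
  }
  if (!identical(dim(mask), dim(a))) stop("mask shape must match counts")
  structure(a, class = "joint_sfs", pops = pops, mask = mask, folded = folded)
}

#' @export
print.joint_sfs <- function(x, ...) {
  n <- dim(x) - 1L
  cat(sprintf("<joint_sfs> %s; %.1f segregating (unmasked)\n",
              paste(sprintf("%s (n=%d)", attr(x, "pops"), n), collapse = " x "),
              sum(x[!attr(x, "mask")])))
  invisible(x)
}

sample_sizes <- function(sfs) dim(sfs) - 1L

# hypergeometric projection matrix from n to m haploids:
# row j+1, col i+1 = P(j derived among m | i derived among n)
projection_matrix <- function(n, m) {
  outer(0:m, 0:n, function(j, i) stats::dhyper(j, i, n - i, m))
}

#' Project a joint SFS to smaller sample sizes
#'
#' Hypergeometric down-sampling along each axis: the projected class `j` is
#' the average over draws of `m` of the `n` haplotypes. A linear operator;
#' total segregating (unmasked) mass cannot increase.
#'
#' @param sfs a [joint_sfs()].
#' @param target_sizes integer vector of new haploid sample sizes, one per
#'   population, each `<=` the current size.
#' @return the projected [joint_sfs()].
#' @export
project_sfs <- function(sfs, target_sizes) {
  n <- sample_sizes(sfs)
  if (length(target_sizes) != length(n)) stop("one target size per population")
  if (any(target_sizes > n)) stop("target size exceeds current sample size")
  a <- unclass(sfs); attributes(a) <- list(dim = dim(sfs))
  for (ax in seq_along(n)) {
    if (target_sizes[ax] == n[ax]) next
    P <- projection_matrix(n[ax], target_sizes[ax])
    a <- apply_axis(a, ax, P)
  }
  joint_sfs(a, pops = attr(sfs, "pops"), folded = attr(sfs, "folded"))
}

# multiply matrix P into axis ax of array a
apply_axis <- function(a, ax, P) {
  d <- dim(a)
  perm <- c(ax, seq_along(d)[-ax])
  m <- matrix(aperm(a, perm), nrow = d[ax])
  m2 <- P %*% m
  d2 <- d; d2[ax] <- nrow(P)
  aperm(array(m2, dim = d2[perm]), order(perm))
}

#' Write a joint SFS as plain text
#'
#' Three lines: the dimensions, the flattened counts in row-major order, and
#' the flattened mask (1 = masked).
#'
#' @param sfs a [joint_sfs()].
#' @param path output file path.
#' @export
write_sfs <- function(sfs, path) {
  d <- dim(sfs)
  rm_order <- function(a) as.vector(aperm(a, rev(seq_along(d))))
  lines <- c(paste(d, collapse = " "),
             paste(format(rm_order(unclass(sfs)), trim = TRUE), collapse = " "),
             paste(as.integer(rm_order(attr(sfs, "mask"))), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a joint SFS written by [write_sfs()]
#'
#' @param path file path.
#' @param pops optional population names.
#' @return a [joint_sfs()].
#' @export
read_sfs <- function(path, pops = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed SFS file")
  d <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  cnt <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  msk <- as.integer(strsplit(trimws(lines[3L]), "\\s+")[[1L]])
  if (length(cnt) != prod(d) || length(msk) != prod(d))
    stop("malformed SFS file: length mismatch")
  unrm <- function(v) aperm(array(v, dim = rev(d)), rev(seq_along(d)))
  joint_sfs(unrm(cnt), pops = pops, mask = unrm(as.logical(msk)))
}
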