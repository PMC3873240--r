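# Joint analysis of IBD segments and local-ancestry calls: segment origin,
# IBD/ancestry consistency, and the switch-density dating signal.

# ancestry labels of one haplotype over [a, b] on a chromosome, as intervals
hap_labels <- function(tracts, ind, hap, chrom, a, b) {
  d <- tracts[tracts$ind == ind & tracts$hap == hap & tracts$chrom == chrom, ]
  d <- d[d$end_cM > a & d$start_cM < b, , drop = FALSE]
  if (!nrow(d)) return(NULL)
  data.frame(start = pmax(d$start_cM, a), end = pmin(d$end_cM, b),
             lab = d$ancestry, stringsAsFactors = FALSE)
}

#' Annotate IBD segments with local-ancestry information
#'
#' For every IBD segment, overlays the ancestry tracts of the two haplotypes
#' involved and reports the majority continental origin, the fraction of the
#' segment where the two haplotypes carry different ancestry labels
#' (mismatch rate), and the number of internal ancestry switch points on the
#' consensus labelling (stretches where the haplotypes agree).
#'
#' @param segments an `ibd_set`.
#' @param ancestry a `tract_set` covering the segment spans.
#' @return data.frame of `IbdAncestryRecord`s: the segment columns plus
#'   `origin` (majority ancestry), `mismatch` (rate in `[0,1]`), `switches`
#'   (integer), `covered` (FALSE when ancestry calls do not cover the span).
#' @export
annotate_ibd_ancestry <- function(segments, ancestry) {
  n <- nrow(segments)
  origin <- character(n); mism <- numeric(n)
  sw <- integer(n); covered <- rep(TRUE, n)
  for (i in seq_len(n)) {
    s <- segments[i, ]
    l1 <- hap_labels(ancestry, s$id1, s$hap1, s$chrom, s$start_cM, s$end_cM)
    l2 <- hap_labels(ancestry, s$id2, s$hap2, s$chrom, s$start_cM, s$end_cM)
    if (is.null(l1) || is.null(l2) ||
        abs(sum(l1$end - l1$start) - s$length_cM) > 1e-6 ||
        abs(sum(l2$end - l2$start) - s$length_cM) > 1e-6) {
      covered[i] <- FALSE; origin[i] <- NA_character_
      mism[i] <- NA_real_; sw[i] <- NA_integer_
      next
    }
    cuts <- sort(unique(c(l1$start, l1$end, l2$start, l2$end)))
    mid <- (cuts[-1] + cuts[-length(cuts)]) / 2
    wid <- diff(cuts)
    a1 <- l1$lab[findInterval(mid, l1$start)]
    a2 <- l2$lab[findInterval(mid, l2$start)]
    agree <- a1 == a2
    mism[i] <- sum(wid[!agree]) / sum(wid)
    # majority origin over both haplotypes
    w <- rowsum(c(wid, wid), c(a1, a2))
    origin[i] <- rownames(w)[which.max(w)]
    # switches: changes in the agreed label sequence
    lab_ok <- a1[agree]
    sw[i] <- if (length(lab_ok) > 1L) sum(lab_ok[-1] != lab_ok[-length(lab_ok)]) else 0L
  }
  out <- cbind(as.data.frame(segments), origin = origin, mismatch = mism,
               switches = sw, covered = covered, stringsAsFactors = FALSE)
  class(out) <- c("ibd_ancestry", "data.frame")
  out
}

#' Trend of ancestry switch-point density with IBD segment length
#'
#' Short IBD segments descend from older common ancestors, leaving less time
#' since admixture onset for recombination to deposit ancestry switch points
#' on them; the density of switch points per cM is therefore expected to
#' increase with segment length. Fits a weighted least-squares slope of
#' switches-per-cM against length (weights = segment length) and computes a
#' one-sided bootstrap p-value by resampling individual pairs as clusters
#' (all segments shared by a pair enter or leave together, preserving their
#' dependence while keeping the null p-value calibrated).
#'
#' @param records output of [annotate_ibd_ancestry()] (>= 10 covered rows).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `slope`, `p` (fraction of bootstrap slopes `<= 0`),
#'   `n_records`, `boot_slopes`.
#' @export
switch_density_trend <- function(records, n_boot = 200, seed = 1) {
  r <- records[records$covered, , drop = FALSE]
  if (nrow(r) < 10L) stop("need at least 10 annotated records")
  if (length(unique(r$length_cM)) < 2L) stop("degenerate: single segment length")
  wls_slope <- function(d) {
    y <- d$switches / d$length_cM
    stats::coef(stats::lm(y ~ d$length_cM, weights = d$length_cM))[[2L]]
  }
  slope <- wls_slope(r)
  pair <- paste(pmin(r$id1, r$id2), pmax(r$id1, r$id2))
  upair <- unique(pair)
  set.seed(as.integer(seed))
  bs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    take <- table(sample(upair, length(upair), replace = TRUE))
    mult <- as.integer(take[pair]); mult[is.na(mult)] <- 0L
    if (sum(mult > 0) < 3L || length(unique(r$length_cM[mult > 0])) < 2L) {
      bs[b] <- NA_real_; next
    }
    d <- r[rep(seq_len(nrow(r)), mult), , drop = FALSE]
    bs[b] <- wls_slope(d)
  }
  bs <- bs[!is.na(bs)]
  list(slope = slope, p = mean(bs <= 0), n_records = nrow(r), boot_slopes = bs)
}

#' Continental origin of the longest IBD segments
#'
#' Counts majority origins among the `top_k` longest segments, separately
#' within and across populations. Ranking is by cM length with deterministic
#' ties broken by chromosome then start position.
#'
#' @param records output of [annotate_ibd_ancestry()] (must carry a `group`
#'   column with values `"within"`/`"across"`).
#' @param top_k number of longest segments to tabulate per group.
#' @return matrix of counts, rows = groups, columns = ancestries.
#' @export
cross_within_summary <- function(records, top_k) {
  r <- records[records$covered, , drop = FALSE]
  out <- matrix(0L, nrow = 2, ncol = length(ANCESTRIES),
                dimnames = list(c("within", "across"), ANCESTRIES))
  if (top_k > nrow(r)) stop("top_k exceeds the number of records")
  for (grp in c("within", "across")) {
    d <- r[r$group == grp, , drop = FALSE]
    if (!nrow(d) || top_k == 0L) next
    o <- order(-d$length_cM, d$chrom, d$start_cM)
    d <- d[o[seq_len(min(top_k, nrow(d)))], , drop = FALSE]
    tb <- table(factor(d$origin, levels = ANCESTRIES))
    out[grp, ] <- as.integer(tb)
  }
  out
}

#' Ancestry composition of non-IBD haplotypes at IBD loci
#'
#' Control for [cross_within_summary()]: at each IBD segment, takes the
#' *other* (non-IBD) haplotype of each of the two individuals over the same
#' span and tabulates majority origins. If the longest IBD segments were of
#' European origin merely because of genome-wide ancestry proportions, the
#' control would show the same excess.
#'
#' @param records output of [annotate_ibd_ancestry()].
#' @param ancestry a `tract_set`.
#' @return matrix of counts, rows = groups, columns = ancestries (two
#'   control haplotypes per record).
#' @export
non_ibd_control <- function(records, ancestry) {
  r <- records[records$covered, , drop = FALSE]
  out <- matrix(0L, nrow = 2, ncol = length(ANCESTRIES),
                dimnames = list(c("within", "across"), ANCESTRIES))
  if (!nrow(r)) return(out)
  for (i in seq_len(nrow(r))) {
    s <- r[i, ]
    for (side in 1:2) {
      id <- if (side == 1) s$id1 else s$id2
      hp <- if (side == 1) s$hap1 else s$hap2
      ll <- hap_labels(ancestry, id, 3L - hp, s$chrom, s$start_cM, s$end_cM)
      if (is.null(ll)) next
      w <- rowsum(ll$end - ll$start, ll$lab)
      lab <- rownames(w)[which.max(w)]
      out[s$group, lab] <- out[s$group, lab] + 1L
    }
  }
  out
}
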