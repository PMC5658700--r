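# Promoter sequence/methylation features: H3K27me3 breadth, GC content,
# CpG-island coverage, metagene profiles, HMR clustering and DMV calling.

#' Breadth of the H3K27me3 domain over a promoter
#'
#' Length (bp) of the longest enriched region overlapping each TSS window;
#' 0 when none overlaps. Intervals are half-open, so a region abutting the
#' window end does not overlap.
#'
#' @param windows BED-like data.frame of TSS windows.
#' @param regions BED-like data.frame of enriched regions.
#' @return numeric vector of breadths, one per window.
#' @export
h3k27me3_breadth <- function(windows, regions) {
  validate_intervals(windows, "windows")
  validate_intervals(regions, "regions")
  win <- bed_to_gr(windows)
  reg <- bed_to_gr(regions)
  hits <- GenomicRanges::findOverlaps(win, reg)
  out <- numeric(length(win))
  if (length(hits) > 0) {
    w <- GenomicRanges::width(reg)[S4Vectors::subjectHits(hits)]
    agg <- tapply(w, S4Vectors::queryHits(hits), max)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' GC fraction of a sequence
#'
#' Proportion of G or C among non-N bases; N bases are excluded from the
#' denominator (assembly gaps carry no sequence information). An all-N
#' sequence returns `NA`.
#'
#' @param seq character vector of sequences over \{A, C, G, T, N\}
#'   (case-insensitive).
#' @return numeric vector of fractions in [0, 1].
#' @export
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) == 0) stop("empty sequence")
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
    if (length(bad) > 0) stop("invalid base(s): ", paste(bad, collapse = ""))
    denom <- sum(ch != "N")
    if (denom == 0) return(NA_real_)
    sum(ch %in% c("G", "C")) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fraction of a target interval covered by CpG islands
#'
#' CpG islands may overlap each other; they are merged before computing
#' covered bases.
#'
#' @param targets BED-like data.frame of target intervals (TSS windows or
#'   gene bodies).
#' @param cgis BED-like data.frame of CpG islands.
#' @return numeric vector of coverage fractions in [0, 1], one per target.
#' @export
cgi_coverage <- function(targets, cgis) {
  validate_intervals(targets, "targets")
  if (nrow(cgis) == 0) return(numeric(nrow(targets)))
  validate_intervals(cgis, "CpG islands")
  tgt <- bed_to_gr(targets)
  cgi <- GenomicRanges::reduce(bed_to_gr(cgis))
  hits <- GenomicRanges::findOverlaps(tgt, cgi)
  out <- numeric(length(tgt))
  if (length(hits) > 0) {
    inter <- GenomicRanges::pintersect(tgt[S4Vectors::queryHits(hits)],
                                       cgi[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(inter)
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
  }
  out / (targets$end - targets$start)
}

#' Metagene coverage profile around anchors
#'
#' Mean coverage in non-overlapping fixed-width bins across windows centered
#' on a set of anchors (TSSs or TESs). Minus-strand profiles are reversed so
#' bins run 5' to 3'. Bins extending beyond chromosome ends are dropped from
#' the per-bin mean (not counted as zero).
#'
#' @param coverage named list of per-base numeric coverage vectors, one per
#'   chromosome (element `i` is the coverage of 0-based position `i - 1`).
#' @param anchors data.frame `chrom`, `pos` (0-based anchor position),
#'   `strand`.
#' @param flank half-width of the profiled window in bp, default 5000.
#' @param bin bin width in bp, default 10.
#' @return numeric vector of per-bin means, length `2 * flank / bin`, ordered
#'   5' to 3'; names give the bin start offset relative to the anchor.
#' @export
metagene_profile <- function(coverage, anchors, flank = 5000L, bin = 10L) {
  stopifnot(flank %% bin == 0, all(c("chrom", "pos", "strand") %in% names(anchors)))
  nbins <- as.integer(2 * flank / bin)
  sums <- numeric(nbins)
  cnts <- numeric(nbins)
  for (i in seq_len(nrow(anchors))) {
    cov <- coverage[[anchors$chrom[i]]]
    if (is.null(cov)) {
      warning("no coverage for chromosome ", anchors$chrom[i])
      next
    }
    start0 <- anchors$pos[i] - flank              # 0-based window start
    binvals <- rep(NA_real_, nbins)
    for (b in seq_len(nbins)) {
      s <- start0 + (b - 1L) * bin
      e <- s + bin                                 # [s, e)
      if (s < 0 || e > length(cov)) next           # beyond chromosome end
      binvals[b] <- mean(cov[(s + 1L):e])
    }
    if (anchors$strand[i] == "-") binvals <- rev(binvals)
    ok <- !is.na(binvals)
    sums[ok] <- sums[ok] + binvals[ok]
    cnts[ok] <- cnts[ok] + 1
  }
  prof <- ifelse(cnts > 0, sums / cnts, NA_real_)
  names(prof) <- seq(-flank, flank - bin, by = bin)
  prof
}

#' Proximity-cluster hypomethylated regions
#'
#' Transitively merges HMRs whose gap is at most `max_gap` bp; output is
#' sorted and disjoint (all remaining gaps exceed `max_gap`). Merging is
#' idempotent and order-invariant.
#'
#' @param hmrs BED-like data.frame of hypomethylated regions.
#' @param max_gap largest gap (bp) bridged by the merge, default 1000.
#' @return BED-like data.frame with an `n_source_hmrs` column.
#' @export
cluster_hmrs <- function(hmrs, max_gap = 1000L) {
  validate_intervals(hmrs, "HMRs")
  gr <- bed_to_gr(hmrs)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  out <- gr_to_bed(merged)
  out$n_source_hmrs <- GenomicRanges::countOverlaps(merged, gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DNA methylation valleys from clustered HMRs
#'
#' Merged hypomethylated intervals at least `min_length` bp long (inclusive
#' cutoff: a 5,000 bp interval is a DMV at the default).
#'
#' @param merged output of [cluster_hmrs()] (sorted, disjoint intervals).
#' @param min_length size cutoff in bp, default 5000.
#' @return subset of `merged` rows qualifying as DMVs.
#' @export
define_dmvs <- function(merged, min_length = 5000L) {
  validate_intervals(merged, "merged HMRs")
  out <- merged[(merged$end - merged$start) >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter DNA-methylation class
#'
#' A promoter window is classified `DMV` if it overlaps a DNA methylation
#' valley, else `hypomethylated` if it overlaps any hypomethylated region,
#' else `methylated`. DMVs should derive from the same HMR set
#' (see [cluster_hmrs()] and [define_dmvs()]).
#'
#' @param windows BED-like data.frame of TSS windows.
#' @param dmvs,hmrs BED-like data.frames.
#' @return character vector in \{"DMV", "hypomethylated", "methylated"\}.
#' @export
promoter_methylation_class <- function(windows, dmvs, hmrs) {
  validate_intervals(windows, "windows")
  win <- bed_to_gr(windows)
  in_dmv <- if (nrow(dmvs) > 0) {
    GenomicRanges::countOverlaps(win, bed_to_gr(dmvs)) > 0
  } else rep(FALSE, length(win))
  in_hmr <- if (nrow(hmrs) > 0) {
    GenomicRanges::countOverlaps(win, bed_to_gr(hmrs)) > 0
  } else rep(FALSE, length(win))
  ifelse(in_dmv, "DMV", ifelse(in_hmr, "hypomethylated", "methylated"))
}
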