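#' Validate a BED-like interval table
#'
#' All genomic intervals in the package use the BED convention: 0-based,
#' half-open `[start, end)` coordinates. A valid interval has a non-empty
#' chromosome name, `start >= 0` and `start < end`.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_intervals <- function(df, what = "interval table") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  bad <- which(is.na(df$chrom) | !nzchar(df$chrom) |
                 is.na(df$start) | is.na(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    stop(sprintf("%s: invalid interval at row %d (chrom='%s', start=%s, end=%s)",
                 what, bad[1], df$chrom[bad[1]],
                 format(df$start[bad[1]]), format(df$end[bad[1]])))
  }
  invisible(df)
}

#' Convert a BED-like table to GRanges
#'
#' Maps 0-based half-open coordinates to the 1-based closed convention used
#' by [GenomicRanges::GRanges]; interval widths are preserved.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `strand`.
#' @return A `GRanges` object with one range per row of `df`.
#' @export
bed_to_gr <- function(df) {
  validate_intervals(df)
  strand <- if ("strand" %in% names(df)) df$strand else rep("*", nrow(df))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Convert GRanges back to a BED-like data.frame
#'
#' @param gr a `GRanges` object.
#' @return data.frame with 0-based half-open `chrom`, `start`, `end`.
#' @export
gr_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Pairwise overlap width between two interval tables
#'
#' Overlap width in bp between interval i of `a` and interval i of `b`
#' (element-wise); 0 when on different chromosomes or disjoint.
#'
#' @param a,b BED-like data.frames of equal row count.
#' @return integer vector of overlap widths.
#' @keywords internal
overlap_width_pairwise <- function(a, b) {
  w <- pmin(a$end, b$end) - pmax(a$start, b$start)
  w[a$chrom != b$chrom] <- 0L
  pmax(w, 0L)
}
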