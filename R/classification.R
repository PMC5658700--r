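# Promoter positivity calls per mark/time point and the eight-state
# classification built from them.

#' Count read starts in windows
#'
#' Number of read 5' start positions falling in each half-open window.
#' Reads are represented by their start position only (no fragment extension).
#'
#' @param read_starts data.frame with `chrom` and `pos` (0-based position).
#' @param windows BED-like data.frame of windows.
#' @return integer vector, one count per window. Windows on chromosomes with
#'   no reads get 0 with a warning (unknown chromosome).
#' @export
count_reads_in_window <- function(read_starts, windows) {
  validate_intervals(windows, "windows")
  stopifnot(all(c("chrom", "pos") %in% names(read_starts)))
  by_chrom <- split(read_starts$pos, read_starts$chrom)
  by_chrom <- lapply(by_chrom, sort)
  unknown <- setdiff(unique(windows$chrom), names(by_chrom))
  if (length(unknown) > 0) {
    warning("no reads on chromosome(s): ", paste(unknown, collapse = ", "),
            "; returning count 0 there")
  }
  out <- integer(nrow(windows))
  for (ch in intersect(unique(windows$chrom), names(by_chrom))) {
    i <- which(windows$chrom == ch)
    pos <- by_chrom[[ch]]
    # reads in [start, end): strictly below end minus strictly below start
    out[i] <- findInterval(windows$end[i] - 1L, pos) -
      findInterval(windows$start[i] - 1L, pos)
  }
  out
}

#' Positivity threshold from overlapping-gene counts
#'
#' The 5th percentile (linear-interpolation quantile, type 7) of the TSS-window
#' read counts of the genes whose window overlaps an enriched region ("5% tail
#' cut"). Computed separately for each (mark, time point).
#'
#' @param counts numeric vector of counts of overlapping genes; must be
#'   non-empty.
#' @param probs tail probability, default 0.05.
#' @return scalar threshold.
#' @export
positivity_threshold <- function(counts, probs = 0.05) {
  if (length(counts) == 0) {
    stop("no overlapping genes for this mark/timepoint: cannot set threshold")
  }
  unname(stats::quantile(counts, probs = probs, type = 7, names = FALSE))
}

#' Call promoters positive/negative for one mark at one time point
#'
#' A promoter is positive when (i) its TSS window overlaps at least one
#' enriched region for the mark and (ii) its read count in the window is above
#' the 5%-tail-cut threshold derived from the overlapping genes. With
#' `inclusive = TRUE` counts equal to the threshold also pass.
#'
#' @param windows data.frame with `gene`, `chrom`, `start`, `end` (TSS
#'   windows of the selected isoforms at this time point).
#' @param regions BED-like data.frame of enriched regions for the mark.
#' @param counts numeric vector of TSS-window read counts, parallel to
#'   `windows` (or named by gene).
#' @param inclusive logical; `FALSE` (default) reads "above a threshold" as
#'   strict.
#' @return data.frame `gene`, `overlapped`, `count`, `status`
#'   ("positive"/"negative"); attributes `threshold` and `n_overlapping`.
#' @export
call_marks <- function(windows, regions, counts, inclusive = FALSE) {
  validate_intervals(windows, "TSS windows")
  validate_intervals(regions, "enriched regions")
  if (!is.null(names(counts))) counts <- counts[windows$gene]
  stopifnot(length(counts) == nrow(windows), !anyNA(counts))
  ov <- GenomicRanges::countOverlaps(bed_to_gr(windows), bed_to_gr(regions)) > 0
  thr <- positivity_threshold(counts[ov])
  pass <- if (inclusive) counts >= thr else counts > thr
  out <- data.frame(gene = windows$gene, overlapped = ov,
                    count = as.numeric(counts),
                    status = ifelse(ov & pass, "positive", "negative"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "n_overlapping") <- sum(ov)
  out
}

#' Exclusion filters for overlapping and internal genes
#'
#' Applied to positive genes of one mark at one time point, in order:
#' \enumerate{
#'   \item window-overlap filter: a positive gene whose TSS window overlaps
#'     another positive gene's TSS window by more than `min_overlap` bp
#'     (default 200 bp, 10\% of the 2-kb window) becomes NA. By default both
#'     genes of such a pair are removed (`remove = "both"`); with
#'     `remove = "lower"` only the gene with the lower count is removed (ties
#'     remove both).
#'   \item internal-gene filter: a still-positive gene whose gene body lies
#'     entirely within another still-positive gene's body becomes NA (the
#'     internal gene only). Two genes with identical bodies are each internal
#'     to the other and both are removed.
#' }
#' The filter is idempotent.
#'
#' @param calls output of [call_marks()].
#' @param windows TSS windows (`gene`, `chrom`, `start`, `end`).
#' @param bodies gene bodies (`gene`, `chrom`, `start`, `end`).
#' @param min_overlap bp of TSS-window overlap tolerated before exclusion.
#' @param remove `"both"` (default) or `"lower"`.
#' @return `calls` with excluded genes' `status` set to `NA`.
#' @export
apply_exclusion_filters <- function(calls, windows, bodies,
                                    min_overlap = 200L,
                                    remove = c("both", "lower")) {
  remove <- match.arg(remove)
  stopifnot(identical(windows$gene, calls$gene),
            identical(bodies$gene, calls$gene))
  status <- calls$status

  # -- window-overlap filter, among positive genes only ----------------------
  pos <- which(!is.na(status) & status == "positive")
  if (length(pos) > 1) {
    gr <- bed_to_gr(windows[pos, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap + 1L,
                                        drop.self = TRUE, drop.redundant = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (length(q) > 0) {
      if (remove == "both") {
        drop <- unique(c(q, s))
      } else {
        cq <- calls$count[pos[q]]
        cs <- calls$count[pos[s]]
        drop <- unique(c(q[cq <= cs], s[cs <= cq]))
      }
      status[pos[drop]] <- NA
    }
  }

  # -- internal-gene filter, among survivors ---------------------------------
  pos <- which(!is.na(status) & status == "positive")
  if (length(pos) > 1) {
    gr <- bed_to_gr(bodies[pos, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(gr, type = "within", drop.self = TRUE)
    inner <- unique(S4Vectors::queryHits(hits))
    status[pos[inner]] <- NA
  }

  calls$status <- status
  calls
}

#' Classify a promoter from its three mark statuses
#'
#' Full truth table on (H3K27me3, S5p, S7p) status triples; any `NA` status
#' yields an `NA` state.
#'
#' @param k27,s5p,s7p character vectors with values "positive", "negative" or
#'   `NA`.
#' @return character vector of promoter state labels (see [PROMOTER_STATES]),
#'   `NA` where any mark is `NA`.
#' @export
classify_state <- function(k27, s5p, s7p) {
  ok <- function(x) is.na(x) | x %in% c("positive", "negative")
  if (!all(ok(k27) & ok(s5p) & ok(s7p))) {
    stop("mark status must be 'positive', 'negative' or NA")
  }
  n <- max(length(k27), length(s5p), length(s7p))
  k27 <- rep_len(k27, n); s5p <- rep_len(s5p, n); s7p <- rep_len(s7p, n)
  key <- paste(k27, s5p, s7p, sep = "|")
  table <- c(
    "positive|positive|negative" = "PRC_S5p",
    "positive|positive|positive" = "PRC_Active",
    "positive|negative|negative" = "PRC_Only",
    "positive|negative|positive" = "PRC_S7p",
    "negative|positive|positive" = "Active",
    "negative|negative|negative" = "Inactive",
    "negative|positive|negative" = "S5p_Only",
    "negative|negative|positive" = "S7p_Only"
  )
  out <- unname(table[key])
  out[is.na(k27) | is.na(s5p) | is.na(s7p)] <- NA_character_
  out
}

#' Classify the whole cohort across marks and time points
#'
#' Runs [call_marks()] and [apply_exclusion_filters()] for each of the three
#' marks at each time point, then assigns promoter states. Genes classified NA
#' for at least one mark at one time point are excluded from the analysis set.
#'
#' @param annotation non-redundant gene table (see [build_nonredundant()]).
#' @param regions nested list `regions[[mark]][[timepoint]]` of BED-like
#'   enriched-region data.frames.
#' @param counts data.frame (`gene`, `mark`, `timepoint`, `count`) of
#'   TSS-window read counts.
#' @param marks,timepoints labels expected in `regions`/`counts`.
#' @param inclusive,min_overlap,remove passed to [call_marks()] and
#'   [apply_exclusion_filters()].
#' @return list with
#'   \describe{
#'     \item{states}{data.frame `gene`, `timepoint`, `k27`, `s5p`, `s7p`,
#'       `state` (long format).}
#'     \item{state_matrix}{genes x time points character matrix of states.}
#'     \item{thresholds}{data.frame `mark`, `timepoint`, `threshold`,
#'       `n_overlapping`.}
#'     \item{analysis_set}{character vector of genes with no NA anywhere.}
#'   }
#' @export
classify_cohort <- function(annotation, regions, counts,
                            marks = MARKS, timepoints = TIMEPOINTS,
                            inclusive = FALSE, min_overlap = 200L,
                            remove = "both") {
  missing_combos <- character()
  for (m in marks) for (tp in timepoints) {
    if (is.null(regions[[m]][[tp]])) {
      missing_combos <- c(missing_combos, paste0(m, "/", tp, " regions"))
    }
    if (!any(counts$mark == m & counts$timepoint == tp)) {
      missing_combos <- c(missing_combos, paste0(m, "/", tp, " counts"))
    }
  }
  if (length(missing_combos) > 0) {
    stop("missing mark/timepoint data: ", paste(missing_combos, collapse = ", "))
  }

  genes <- sort(unique(annotation$cluster_id))
  thresholds <- list()
  status_arr <- array(NA_character_, dim = c(length(genes), length(timepoints),
                                             length(marks)),
                      dimnames = list(genes, timepoints, marks))
  for (tp in timepoints) {
    ann_tp <- annotation[annotation$timepoint == tp, , drop = FALSE]
    ann_tp <- ann_tp[match(genes, ann_tp$cluster_id), , drop = FALSE]
    windows <- data.frame(gene = genes, chrom = ann_tp$chrom,
                          start = ann_tp$tss_start, end = ann_tp$tss_end,
                          stringsAsFactors = FALSE)
    bodies <- data.frame(gene = genes, chrom = ann_tp$chrom,
                         start = ann_tp$body_start, end = ann_tp$body_end,
                         stringsAsFactors = FALSE)
    for (m in marks) {
      sub <- counts[counts$mark == m & counts$timepoint == tp, , drop = FALSE]
      cnt <- stats::setNames(sub$count, sub$gene)
      if (!all(genes %in% names(cnt))) {
        stop("missing counts for ", sum(!(genes %in% names(cnt))),
             " gene(s) at ", m, "/", tp)
      }
      calls <- call_marks(windows, regions[[m]][[tp]], cnt[genes],
                          inclusive = inclusive)
      calls <- apply_exclusion_filters(calls, windows, bodies,
                                       min_overlap = min_overlap,
                                       remove = remove)
      status_arr[, tp, m] <- calls$status
      thresholds[[paste(m, tp)]] <- data.frame(
        mark = m, timepoint = tp,
        threshold = attr(calls, "threshold"),
        n_overlapping = attr(calls, "n_overlapping"),
        stringsAsFactors = FALSE)
    }
  }

  long <- expand.grid(gene = genes, timepoint = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$k27 <- status_arr[cbind(long$gene, long$timepoint, "H3K27me3")]
  long$s5p <- status_arr[cbind(long$gene, long$timepoint, "S5p")]
  long$s7p <- status_arr[cbind(long$gene, long$timepoint, "S7p")]
  long$state <- classify_state(long$k27, long$s5p, long$s7p)

  state_matrix <- matrix(long$state, nrow = length(genes),
                         dimnames = list(genes, timepoints))
  analysis_set <- genes[rowSums(is.na(state_matrix)) == 0]

  list(states = long,
       state_matrix = state_matrix,
       thresholds = do.call(rbind, c(thresholds, list(make.row.names = FALSE))),
       analysis_set = analysis_set)
}
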