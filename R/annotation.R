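# Non-redundant gene list construction: filter gene clusters, derive TSS/TES
# windows, and pick one representative isoform per cluster per time point.

#' Ordered differentiation time points
#'
#' The default time course: embryonic stem cells, then days 1, 3, 16 and 30 of
#' neuronal differentiation.
#' @export
TIMEPOINTS <- c("ESC", "day1", "day3", "day16", "day30")

#' Promoter state labels
#'
#' The eight promoter states defined by the presence/absence of H3K27me3,
#' RNAPII-S5p and RNAPII-S7p at the TSS window.
#' @export
PROMOTER_STATES <- c("Active", "Inactive", "PRC_Only", "PRC_S5p", "PRC_Active",
                     "S5p_Only", "S7p_Only", "PRC_S7p")

#' The three chromatin marks used for classification
#' @export
MARKS <- c("H3K27me3", "S5p", "S7p")

#' Read a knownGene-like isoform table
#'
#' Expected columns: `isoform_id`, `cluster_id`, `chrom`, `strand`, `txStart`,
#' `txEnd`, `cdsStart`, `cdsEnd`, `refseq_flag`, `canonical_flag`.
#' Coordinates are 0-based half-open, UCSC style.
#'
#' @param path TSV path.
#' @return validated isoform data.frame.
#' @export
read_isoform_table <- function(path) {
  df <- read_tsv_table(path)
  validate_isoform_table(df)
}

#' @keywords internal
validate_isoform_table <- function(df) {
  need <- c("isoform_id", "cluster_id", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "refseq_flag", "canonical_flag")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("isoform table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(df$chrom) | !nzchar(df$chrom) |
                 is.na(df$cluster_id) | !nzchar(as.character(df$cluster_id)))
  if (length(bad) > 0) {
    stop(sprintf("malformed isoform table row %d: missing chrom or cluster id",
                 bad[1]))
  }
  if (any(df$cdsStart > df$cdsEnd)) {
    stop("isoform table has cdsStart > cdsEnd")
  }
  df$refseq_flag <- as.logical(df$refseq_flag)
  df$canonical_flag <- as.logical(df$canonical_flag)
  df
}

#' Filter gene clusters before isoform selection
#'
#' Removes clusters located on the mitochondrial chromosome (`chrM`) or on
#' "random" assembly scaffolds (chromosome names ending in `_random`), and
#' clusters with no RefSeq-linked isoform. A cluster is removed as a whole if
#' any of its isoforms triggers the chromosome filter.
#'
#' @param iso isoform table (see [read_isoform_table()]).
#' @return the retained rows; attribute `removed_clusters` holds a data.frame
#'   of removed cluster ids and the reason.
#' @export
filter_clusters <- function(iso) {
  iso <- validate_isoform_table(iso)
  bad_chrom <- iso$chrom == "chrM" | grepl("_random$", iso$chrom)
  bad_chrom_clusters <- unique(iso$cluster_id[bad_chrom])
  refseq_by_cluster <- tapply(iso$refseq_flag, iso$cluster_id, any)
  no_refseq_clusters <- names(refseq_by_cluster)[!refseq_by_cluster]
  no_refseq_clusters <- setdiff(no_refseq_clusters, bad_chrom_clusters)
  keep <- !(iso$cluster_id %in% c(bad_chrom_clusters, no_refseq_clusters))
  out <- iso[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- rbind(
    if (length(bad_chrom_clusters) > 0)
      data.frame(cluster_id = bad_chrom_clusters, reason = "chrM_or_random",
                 stringsAsFactors = FALSE),
    if (length(no_refseq_clusters) > 0)
      data.frame(cluster_id = no_refseq_clusters, reason = "no_refseq",
                 stringsAsFactors = FALSE)
  )
  attr(out, "removed_clusters") <-
    if (is.null(removed)) data.frame(cluster_id = character(), reason = character())
    else removed
  out
}

#' TSS window
#'
#' Fixed-width window centered on the transcription start site: `txStart` for
#' plus-strand and `txEnd` for minus-strand transcripts. The window is clamped
#' at chromosome start 0 (the downstream edge is kept, so a clamped window is
#' shorter than `width`).
#'
#' @param tx_start,tx_end transcript coordinates (0-based half-open).
#' @param strand `+` or `-` (vectorized).
#' @param width window width in bp; even, positive. Default 2000.
#' @return data.frame with `start`, `end`.
#' @export
tss_window <- function(tx_start, tx_end, strand, width = 2000L) {
  stopifnot(width > 0, width %% 2 == 0)
  anchor <- ifelse(strand == "+", tx_start, tx_end)
  data.frame(start = pmax(0L, as.integer(anchor - width / 2)),
             end = as.integer(anchor + width / 2))
}

#' TES window
#'
#' Fixed-width window centered on the transcription end site (`txEnd` for
#' plus-strand, `txStart` for minus-strand transcripts), clamped at 0.
#'
#' @inheritParams tss_window
#' @param width window width in bp; default 4000.
#' @export
tes_window <- function(tx_start, tx_end, strand, width = 4000L) {
  stopifnot(width > 0, width %% 2 == 0)
  anchor <- ifelse(strand == "+", tx_end, tx_start)
  data.frame(start = pmax(0L, as.integer(anchor - width / 2)),
             end = as.integer(anchor + width / 2))
}

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never perturbs user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic per-identifier seed offset
#' @keywords internal
id_seed <- function(seed, id) {
  (as.integer(seed) + sum(utf8ToInt(as.character(id))) * 131L) %% 2147483647L
}

#' Select the representative isoform of one gene cluster
#'
#' Applies the selection cascade: (single isoform) else highest RNAPII-S5p
#' TSS-window count, then highest RNAPII-S2p TES-window count among the tied
#' survivors (skipped when S2p counts are absent), then the unique canonical
#' isoform among survivors, then a seeded random draw. Each step is applied
#' only to the survivors of the previous step's tie; the random step sorts
#' survivors lexicographically before drawing, so it is invariant to input
#' order.
#'
#' @param isoform_ids character vector of the cluster's isoform ids.
#' @param s5p_counts named numeric: S5p TSS-window counts per isoform
#'   (required when the cluster has more than one isoform).
#' @param s2p_counts named numeric or `NULL`: S2p TES-window counts.
#' @param canonical_ids character vector of canonical isoform ids.
#' @param rng_seed integer seed for the random step.
#' @return list with `isoform_id` and `step` in
#'   `{"single","s5p","s2p","canonical","random"}`.
#' @export
select_isoform <- function(isoform_ids, s5p_counts = NULL, s2p_counts = NULL,
                           canonical_ids = character(), rng_seed = 1L) {
  isoform_ids <- as.character(isoform_ids)
  if (length(isoform_ids) == 0) stop("empty cluster: no isoforms to select from")
  if (length(isoform_ids) == 1) {
    return(list(isoform_id = isoform_ids, step = "single"))
  }
  if (is.null(s5p_counts) || !all(isoform_ids %in% names(s5p_counts))) {
    stop("S5p counts must be supplied for every isoform of a multi-isoform cluster")
  }
  survivors <- isoform_ids
  cnt <- s5p_counts[survivors]
  survivors <- survivors[cnt == max(cnt)]
  if (length(survivors) == 1) {
    return(list(isoform_id = survivors, step = "s5p"))
  }
  if (!is.null(s2p_counts)) {
    if (!all(survivors %in% names(s2p_counts))) {
      stop("S2p counts supplied but missing for some isoforms of the cluster")
    }
    cnt <- s2p_counts[survivors]
    survivors <- survivors[cnt == max(cnt)]
    if (length(survivors) == 1) {
      return(list(isoform_id = survivors, step = "s2p"))
    }
  }
  canon <- intersect(survivors, canonical_ids)
  if (length(canon) == 1) {
    return(list(isoform_id = canon, step = "canonical"))
  }
  # 0 or >= 2 canonical flags among survivors: fall through to seeded random
  survivors <- sort(survivors)
  pick <- with_seed(rng_seed, sample.int(length(survivors), 1L))
  list(isoform_id = survivors[pick], step = "random")
}

#' Build the non-redundant gene table
#'
#' For every retained cluster and every time point, selects a representative
#' isoform via [select_isoform()] and derives its TSS (2 kb) and TES (4 kb)
#' windows and gene body.
#'
#' @param iso filtered isoform table (see [filter_clusters()]).
#' @param s5p_counts data.frame (`isoform_id`, `timepoint`, `count`) of S5p
#'   reads in isoform TSS windows, or `NULL` when all clusters are
#'   single-isoform.
#' @param s2p_counts data.frame (`isoform_id`, `timepoint`, `count`) of S2p
#'   reads in isoform TES windows, or `NULL` (cascade skips that step).
#' @param timepoints ordered time point labels.
#' @param tss_width,tes_width window widths in bp.
#' @param seed integer seed for the random cascade step; the draw for each
#'   cluster is offset deterministically from its id so results do not depend
#'   on cluster order.
#' @return data.frame, one row per cluster x time point: `cluster_id`,
#'   `timepoint`, `isoform_id`, `selection_step`, `chrom`, `strand`,
#'   `tss_start`, `tss_end`, `tes_start`, `tes_end`, `body_start`, `body_end`.
#' @export
build_nonredundant <- function(iso, s5p_counts = NULL, s2p_counts = NULL,
                               timepoints = TIMEPOINTS,
                               tss_width = 2000L, tes_width = 4000L,
                               seed = 1L) {
  iso <- validate_isoform_table(iso)
  canonical_ids <- iso$isoform_id[iso$canonical_flag]
  clusters <- split(seq_len(nrow(iso)), iso$cluster_id)

  count_map <- function(counts, tp) {
    if (is.null(counts)) return(NULL)
    sub <- counts[counts$timepoint == tp, , drop = FALSE]
    stats::setNames(sub$count, sub$isoform_id)
  }

  rows <- vector("list", length(clusters) * length(timepoints))
  k <- 0L
  for (cl in names(clusters)) {
    idx <- clusters[[cl]]
    ids <- iso$isoform_id[idx]
    for (tp in timepoints) {
      sel <- select_isoform(
        ids,
        s5p_counts = count_map(s5p_counts, tp),
        s2p_counts = count_map(s2p_counts, tp),
        canonical_ids = canonical_ids,
        rng_seed = id_seed(seed, paste0(cl, ":", tp))
      )
      i <- idx[match(sel$isoform_id, ids)]
      tssw <- tss_window(iso$txStart[i], iso$txEnd[i], iso$strand[i], tss_width)
      tesw <- tes_window(iso$txStart[i], iso$txEnd[i], iso$strand[i], tes_width)
      k <- k + 1L
      rows[[k]] <- data.frame(
        cluster_id = cl, timepoint = tp,
        isoform_id = sel$isoform_id, selection_step = sel$step,
        chrom = iso$chrom[i], strand = iso$strand[i],
        tss_start = tssw$start, tss_end = tssw$end,
        tes_start = tesw$start, tes_end = tesw$end,
        body_start = iso$txStart[i], body_end = iso$txEnd[i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}
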