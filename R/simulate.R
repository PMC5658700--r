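# Synthetic multi-omics cohort with planted ground truth: annotation with
# decoy clusters, per-mark enriched regions and TSS-window counts, coupled
# TPM and knockout tables, CGI/HMR tracks and TF influence ranks.

# Planted trajectory archetypes (states at ESC, day1, day3, day16, day30).
# The default mixture mirrors the qualitative structure of the study system:
# roughly 31% of promoters Polycomb-marked in ESCs, ~81% of those co-occupied
# by S5p, Maintained + Lost equal to the ESC-positive count, and poised
# promoters that either keep their state, lose S5p, resolve to Inactive or
# activate during differentiation.
ARCHETYPE_STATES <- rbind(
  always_active        = c("Active", "Active", "Active", "Active", "Active"),
  always_inactive      = c("Inactive", "Inactive", "Inactive", "Inactive", "Inactive"),
  always_prcs5p        = c("PRC_S5p", "PRC_S5p", "PRC_S5p", "PRC_S5p", "PRC_S5p"),
  prcs5p_to_prconly    = c("PRC_S5p", "PRC_S5p", "PRC_Only", "PRC_Only", "PRC_Only"),
  prcs5p_to_inactive   = c("PRC_S5p", "PRC_S5p", "PRC_S5p", "Inactive", "Inactive"),
  prcs5p_to_active     = c("PRC_S5p", "PRC_S5p", "PRC_Active", "Active", "Active"),
  prconly_lost         = c("PRC_Only", "PRC_Only", "Inactive", "Inactive", "Inactive"),
  acquired_d1_transient = c("Inactive", "PRC_Only", "PRC_Only", "Inactive", "Inactive"),
  acquired_d16         = c("Inactive", "Inactive", "Inactive", "PRC_Only", "PRC_Only"),
  acquired_d30         = c("Active", "Active", "Active", "Active", "PRC_Active")
)
colnames(ARCHETYPE_STATES) <- TIMEPOINTS

# mark positivity implied by each promoter state (H3K27me3, S5p, S7p)
STATE_FLAGS <- rbind(
  Active     = c(FALSE, TRUE, TRUE),
  Inactive   = c(FALSE, FALSE, FALSE),
  PRC_Only   = c(TRUE, FALSE, FALSE),
  PRC_S5p    = c(TRUE, TRUE, FALSE),
  PRC_Active = c(TRUE, TRUE, TRUE),
  S5p_Only   = c(FALSE, TRUE, FALSE),
  S7p_Only   = c(FALSE, FALSE, TRUE),
  PRC_S7p    = c(TRUE, FALSE, TRUE)
)
colnames(STATE_FLAGS) <- MARKS

#' Simulation configuration
#'
#' Defaults define the study conditions emulated by the generator: a small
#' two-chromosome genome, 1,000 gene clusters, a trajectory-group mixture with
#' ~31\% ESC Polycomb-positive promoters of which ~81\% are S5p co-occupied,
#' well-separated negative-binomial TSS-window counts, lognormal TPM coupled
#' to S7p, knockout upregulation probabilities of 0.30 (PRC/S5p) vs 0.05
#' (PRC Only), methylation-valley membership of 0.65 for always-poised vs
#' 0.02 for resolving-to-Inactive promoters, and influence-rank bias favoring
#' the planted poised TFs.
#'
#' @param n_genes number of real gene clusters.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param fractions named fractions of the trajectory archetypes (see
#'   `rownames(ARCHETYPE_STATES)`); the unlisted remainder is always_inactive.
#' @param multi_isoform_fraction fraction of clusters given 1-3 extra
#'   isoforms.
#' @param overlap_fraction fraction of genes given a companion gene whose TSS
#'   window overlaps theirs (exercises the window-overlap filter).
#' @param nested_fraction fraction of genes given a companion gene nested in
#'   their body (exercises the internal-gene filter).
#' @param gene_length_range min/max gene body length (bp).
#' @param count_mu_pos,count_size_pos negative-binomial mean/size of
#'   TSS-window counts at planted-positive promoters.
#' @param count_mu_bg,count_size_bg background counts at promoters with no
#'   enriched region.
#' @param p_decoy_region probability that a planted-negative promoter is
#'   covered by an enriched region with a zero count (these decoys pin the 5\%
#'   tail cut at zero).
#' @param region_width,region_width_broad enriched-region widths (bp); the
#'   broad width applies to H3K27me3 at always-poised promoters (3x the
#'   default, emulating their broader Polycomb domains).
#' @param tpm_meanlog_active,tpm_meanlog_poised,tpm_meanlog_silent,tpm_sdlog
#'   lognormal TPM parameters by promoter class.
#' @param peak_fraction fraction of always-active genes given a single-time-
#'   point expression peak.
#' @param peak_fold fold elevation of the peak time point.
#' @param ko_upregulation_prob named per-ESC-state probabilities of knockout
#'   derepression.
#' @param p_wt_high_repressed fraction of repressed-state genes planted with
#'   wild-type expression above 1 FPKM (exercises the exclusion rule).
#' @param p_dmv named methylation-valley membership probabilities for the
#'   three poised-fate groups and all other genes.
#' @param n_tf_per_state TFs sampled per day-30 promoter state for the
#'   influence-rank tables.
#' @param n_conversions number of cell-type conversions ranked.
#' @param rank_bias latent-score shift making planted poised TFs more
#'   influential (0 = null ranks).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L,
                       chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                       fractions = c(always_active = 0.30,
                                     always_prcs5p = 0.055,
                                     prcs5p_to_prconly = 0.060,
                                     prcs5p_to_inactive = 0.045,
                                     prcs5p_to_active = 0.090,
                                     prconly_lost = 0.060,
                                     acquired_d1_transient = 0.050,
                                     acquired_d16 = 0.050,
                                     acquired_d30 = 0.040),
                       multi_isoform_fraction = 0.25,
                       overlap_fraction = 0,
                       nested_fraction = 0,
                       gene_length_range = c(2000L, 8000L),
                       count_mu_pos = 150, count_size_pos = 20,
                       count_mu_bg = 20, count_size_bg = 10,
                       p_decoy_region = 0.2,
                       region_width = 2000L, region_width_broad = 6000L,
                       tpm_meanlog_active = log(30),
                       tpm_meanlog_poised = log(0.2),
                       tpm_meanlog_silent = log(0.05),
                       tpm_sdlog = 0.5,
                       peak_fraction = 0.10, peak_fold = 100,
                       ko_upregulation_prob = c(PRC_S5p = 0.30,
                                                PRC_Only = 0.05,
                                                Active = 0.02,
                                                Inactive = 0.02),
                       p_wt_high_repressed = 0.05,
                       p_dmv = c(always_prcs5p = 0.65,
                                 to_prc_only = 0.13,
                                 to_inactive = 0.02,
                                 other = 0.02),
                       n_tf_per_state = 40L,
                       n_conversions = 8L,
                       rank_bias = 1.5) {
  bad <- setdiff(names(fractions), rownames(ARCHETYPE_STATES))
  if (length(bad) > 0) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  if (any(fractions < 0) || sum(fractions) > 1) {
    stop("archetype fractions must be non-negative and sum to at most 1")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
assign_archetypes <- function(config) {
  n <- config$n_genes
  counts <- round(config$fractions * n)
  filler <- n - sum(counts)
  if (filler < 0) { # rounding overshoot: trim the largest group
    i <- which.max(counts)
    counts[i] <- counts[i] + filler
    filler <- 0
  }
  rep(c(names(counts), "always_inactive"), c(counts, filler))
}

#' Generate the synthetic isoform/annotation table
#'
#' Lays real gene clusters out on the configured chromosomes with generous,
#' even spacing (no two TSS windows overlap unless `overlap_fraction` or
#' `nested_fraction` requests companion genes), adds extra isoforms to a
#' fraction of clusters, and appends three decoy clusters (chrM, a `_random`
#' scaffold, and a cluster without RefSeq linkage) that the annotation filter
#' must remove.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `isoforms` (knownGene-like table), `genes` (per real
#'   gene: id, chrom, strand, body, tss), and `s5p_isoform_counts`
#'   (isoform-level S5p TSS counts used by the selection cascade; the primary
#'   isoform always wins).
#' @export
generate_annotation <- function(config, seed = 1L) {
  with_seed(seed, {
    n <- config$n_genes
    chroms <- names(config$chrom_sizes)
    per_chrom <- diff(round(seq(0, n, length.out = length(chroms) + 1)))
    margin <- 20000L
    slot <- floor((config$chrom_sizes - 2 * margin) / pmax(per_chrom, 1L))
    if (any(per_chrom > 0 & slot < 12000)) {
      stop("infeasible packing: chromosome too short for requested gene count")
    }
    gene_id <- sprintf("g%04d", seq_len(n))
    chrom <- rep(chroms, per_chrom)
    idx_in_chrom <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
    pos <- margin + (idx_in_chrom - 1L) * slot[chrom]
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                  n, replace = TRUE)
    tx_start <- as.integer(pos)
    tx_end <- as.integer(pos + len)
    tss <- ifelse(strand == "+", tx_start, tx_end)

    iso <- data.frame(
      isoform_id = paste0(gene_id, ".1"), cluster_id = gene_id,
      chrom = chrom, strand = strand, txStart = tx_start, txEnd = tx_end,
      cdsStart = tx_start + 100L, cdsEnd = tx_end - 100L,
      refseq_flag = TRUE, canonical_flag = TRUE, stringsAsFactors = FALSE
    )

    # extra isoforms: TSS shifted downstream within the body; never selected
    # because their S5p counts are capped strictly below the primary's
    multi <- which(stats::runif(n) < config$multi_isoform_fraction & len >= 4000)
    extra <- lapply(multi, function(i) {
      k <- sample(1:3, 1)
      shift <- sort(sample(seq(1000L, len[i] - 1000L), k))
      data.frame(
        isoform_id = paste0(gene_id[i], ".", 1 + seq_len(k)),
        cluster_id = gene_id[i], chrom = chrom[i], strand = strand[i],
        txStart = if (strand[i] == "+") tx_start[i] + shift else tx_start[i],
        txEnd = if (strand[i] == "+") tx_end[i] else tx_end[i] - shift,
        cdsStart = tx_start[i] + 100L + (strand[i] == "+") * shift,
        cdsEnd = tx_end[i] - 100L - (strand[i] == "-") * shift,
        refseq_flag = TRUE, canonical_flag = FALSE, stringsAsFactors = FALSE
      )
    })

    # companion genes exercising the exclusion filters
    companions <- list()
    mk_companion <- function(host, id, txs, txe) {
      data.frame(isoform_id = paste0(id, ".1"), cluster_id = id,
                 chrom = chrom[host], strand = strand[host],
                 txStart = as.integer(txs), txEnd = as.integer(txe),
                 cdsStart = as.integer(txs), cdsEnd = as.integer(txe),
                 refseq_flag = TRUE, canonical_flag = TRUE,
                 stringsAsFactors = FALSE)
    }
    if (config$overlap_fraction > 0) {
      hosts <- which(stats::runif(n) < config$overlap_fraction)
      companions <- c(companions, lapply(seq_along(hosts), function(j) {
        i <- hosts[j]
        off <- sample(200:1900, 1)  # TSS-window overlap of 2000 - off bp
        t2 <- tss[i] + off
        if (strand[i] == "+") mk_companion(i, sprintf("ovl%04d", j), t2, t2 + 1500L)
        else mk_companion(i, sprintf("ovl%04d", j), t2 - 1500L, t2)
      }))
    }
    if (config$nested_fraction > 0) {
      hosts <- which(stats::runif(n) < config$nested_fraction & len >= 4000)
      companions <- c(companions, lapply(seq_along(hosts), function(j) {
        i <- hosts[j]
        mk_companion(i, sprintf("nst%04d", j),
                     tx_start[i] + floor(len[i] / 4),
                     tx_start[i] + floor(len[i] / 2))
      }))
    }

    decoys <- data.frame(
      isoform_id = c("decoyM.1", "decoyR.1", "decoyX.1"),
      cluster_id = c("decoyM", "decoyR", "decoyX"),
      chrom = c("chrM", paste0(chroms[1], "_random"), chroms[1]),
      strand = "+",
      txStart = c(1000L, 1000L, 5000L), txEnd = c(3000L, 3000L, 7000L),
      cdsStart = c(1000L, 1000L, 5000L), cdsEnd = c(3000L, 3000L, 7000L),
      refseq_flag = c(TRUE, TRUE, FALSE), canonical_flag = TRUE,
      stringsAsFactors = FALSE
    )

    isoforms <- do.call(rbind, c(list(iso), extra, companions, list(decoys)))
    rownames(isoforms) <- NULL

    # isoform-level S5p counts: primary isoform strictly above any alternate
    counts <- do.call(rbind, lapply(TIMEPOINTS, function(tp) {
      primary <- grepl("\\.1$", isoforms$isoform_id)
      cnt <- integer(nrow(isoforms))
      cnt[primary] <- 200L + stats::rnbinom(sum(primary), mu = 100, size = 20)
      cnt[!primary] <- pmin(stats::rnbinom(sum(!primary), mu = 30, size = 10), 150L)
      data.frame(isoform_id = isoforms$isoform_id, timepoint = tp,
                 count = cnt, stringsAsFactors = FALSE)
    }))

    companion_ids <- unlist(lapply(companions, function(d) d$cluster_id[1]))
    genes <- data.frame(gene = c(gene_id, companion_ids),
                        stringsAsFactors = FALSE)
    all_primary <- isoforms[match(paste0(genes$gene, ".1"), isoforms$isoform_id), ]
    genes$chrom <- all_primary$chrom
    genes$strand <- all_primary$strand
    genes$body_start <- all_primary$txStart
    genes$body_end <- all_primary$txEnd
    genes$tss <- ifelse(genes$strand == "+", genes$body_start, genes$body_end)
    genes$companion <- !(genes$gene %in% gene_id)

    list(isoforms = isoforms, genes = genes, s5p_isoform_counts = counts)
  })
}

#' Generate enriched regions and TSS-window counts from planted states
#'
#' For every planted-positive (gene, mark, time point) an enriched region
#' covers the TSS window (3x broader H3K27me3 domains at always-poised genes)
#' and the count comes from the high negative-binomial component. Planted
#' negatives either carry no region (background count) or, with probability
#' `p_decoy_region`, a region with a zero count; these decoys anchor the 5th
#' percentile of the overlapping-count distribution at zero, so the tail cut
#' removes exactly them. Marks with no planted positives at a time point get
#' no regions at all.
#'
#' @param truth data.frame with `gene`, `archetype` and planted state columns
#'   (`state_ESC` ... ).
#' @param genes gene geometry from [generate_annotation()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list `regions[[mark]][[timepoint]]` (BED-like) and `counts`
#'   (long data.frame `gene`, `mark`, `timepoint`, `count`).
#' @export
generate_mark_data <- function(truth, genes, config, seed = 1L) {
  with_seed(seed, {
    stopifnot(identical(truth$gene, genes$gene))
    regions <- stats::setNames(vector("list", length(MARKS)), MARKS)
    counts <- list()
    for (m in MARKS) {
      regions[[m]] <- stats::setNames(vector("list", length(TIMEPOINTS)),
                                      TIMEPOINTS)
      for (tp in TIMEPOINTS) {
        st <- truth[[paste0("state_", tp)]]
        pos <- STATE_FLAGS[st, m]
        broad <- m == "H3K27me3" & truth$archetype == "always_prcs5p"
        w <- ifelse(broad, config$region_width_broad, config$region_width)
        cnt <- integer(nrow(truth))
        has_region <- pos
        if (any(pos)) {
          cnt[pos] <- stats::rnbinom(sum(pos), mu = config$count_mu_pos,
                                     size = config$count_size_pos)
          decoy <- !pos & stats::runif(nrow(truth)) < config$p_decoy_region
          has_region <- pos | decoy
          cnt[decoy] <- 0L
          bg <- !has_region
          cnt[bg] <- stats::rnbinom(sum(bg), mu = config$count_mu_bg,
                                    size = config$count_size_bg)
        } else {
          cnt <- stats::rnbinom(nrow(truth), mu = config$count_mu_bg,
                                size = config$count_size_bg)
          has_region <- rep(FALSE, nrow(truth))
        }
        reg <- data.frame(
          chrom = genes$chrom[has_region],
          start = pmax(0L, as.integer(genes$tss[has_region] - w[has_region] / 2)),
          end = as.integer(genes$tss[has_region] + w[has_region] / 2),
          stringsAsFactors = FALSE
        )
        reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
        rownames(reg) <- NULL
        regions[[m]][[tp]] <- reg
        counts[[paste(m, tp)]] <- data.frame(
          gene = truth$gene, mark = m, timepoint = tp, count = cnt,
          stringsAsFactors = FALSE)
      }
    }
    list(regions = regions,
         counts = do.call(rbind, c(counts, list(make.row.names = FALSE))))
  })
}

#' Generate a coupled TPM matrix and knockout expression table
#'
#' TPM follows the planted promoter state at each time point: S7p-positive
#' states draw from a high lognormal, poised (S5p without S7p) states from a
#' near-zero lognormal, silent states lower still. A fraction of
#' always-active genes receives one strongly inflated time point (the planted
#' expression peak). The knockout table flips planted derepressed genes above
#' the fold-change and knockout-expression thresholds with per-ESC-state
#' probabilities; a small fraction of repressed-state genes is planted with
#' wild-type expression above 1 FPKM to exercise the exclusion rule.
#'
#' @inheritParams generate_mark_data
#' @return list `tpm` (matrix genes x time points), `ko` (data.frame `gene`,
#'   `wt_expr`, `ko_expr`), and updated truth columns `peak_timepoint`,
#'   `ko_upregulated`, `ko_excluded`.
#' @export
generate_expression <- function(truth, config, seed = 1L) {
  with_seed(seed, {
    n <- nrow(truth)
    tpm <- matrix(0, nrow = n, ncol = length(TIMEPOINTS),
                  dimnames = list(truth$gene, TIMEPOINTS))
    for (tp in TIMEPOINTS) {
      st <- truth[[paste0("state_", tp)]]
      s7p <- STATE_FLAGS[st, "S7p"]
      s5p <- STATE_FLAGS[st, "S5p"]
      meanlog <- ifelse(s7p, config$tpm_meanlog_active,
                        ifelse(s5p, config$tpm_meanlog_poised,
                               config$tpm_meanlog_silent))
      tpm[, tp] <- stats::rlnorm(n, meanlog = meanlog, sdlog = config$tpm_sdlog)
    }

    truth$peak_timepoint <- NA_character_
    aa <- which(truth$archetype == "always_active")
    n_peak <- round(length(aa) * config$peak_fraction)
    if (n_peak > 0) {
      peak_genes <- sample(aa, n_peak)
      peak_tp <- sample(TIMEPOINTS, n_peak, replace = TRUE)
      base <- 2 * stats::rlnorm(n_peak * length(TIMEPOINTS), 0, 0.1)
      tpm[peak_genes, ] <- matrix(base, nrow = n_peak)
      tpm[cbind(peak_genes, match(peak_tp, TIMEPOINTS))] <- 2 * config$peak_fold
      truth$peak_timepoint[peak_genes] <- peak_tp
    }

    esc_state <- truth$state_ESC
    repressed <- esc_state %in% c("PRC_S5p", "PRC_Only", "Inactive")
    wt <- numeric(n)
    wt[repressed] <- stats::runif(sum(repressed), 0.05, 0.8)
    wt[!repressed] <- stats::rlnorm(sum(!repressed), log(5), 0.5)
    high_wt <- repressed & stats::runif(n) < config$p_wt_high_repressed
    wt[high_wt] <- stats::runif(sum(high_wt), 1.5, 3)
    truth$ko_excluded <- high_wt

    p_up <- config$ko_upregulation_prob[esc_state]
    p_up[is.na(p_up)] <- 0.02
    up <- !high_wt & stats::runif(n) < p_up
    ko <- ifelse(up, pmax(wt, 0.5) * stats::runif(n, 3, 8),
                 wt * stats::runif(n, 0.5, 1.4))
    truth$ko_upregulated <- up

    list(tpm = tpm,
         ko = data.frame(gene = truth$gene, wt_expr = wt, ko_expr = ko,
                         stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate CpG-island and hypomethylated-region tracks and TF influence ranks
#'
#' Always-poised genes receive wide CpG islands and, with the configured
#' probability, a cluster of hypomethylated regions spanning ~8 kb around the
#' TSS (merging into a methylation valley); non-valley always-poised genes get
#' a single small hypomethylated region, so every always-poised promoter is
#' hypomethylated. Resolving-to-Inactive genes are mostly methylated.
#' Influence-rank tables rank a TF panel (sampled per day-30 promoter state)
#' over several conversions, with planted poised TFs biased toward low
#' (influential) ranks.
#'
#' @inheritParams generate_mark_data
#' @return list `cgi`, `hmr` (BED-like), `tf_ranks` (data.frame `tf`,
#'   `conversion`, `rank`), `tf_panel` (data.frame `tf`, `day30_state`,
#'   `planted_poised`), and updated truth column `dmv_member`.
#' @export
generate_tracks_and_ranks <- function(truth, genes, config, seed = 1L) {
  with_seed(seed, {
    stopifnot(identical(truth$gene, genes$gene))
    n <- nrow(truth)
    group <- ifelse(truth$archetype == "always_prcs5p", "always_prcs5p",
                    ifelse(truth$archetype == "prcs5p_to_prconly", "to_prc_only",
                           ifelse(truth$archetype == "prcs5p_to_inactive",
                                  "to_inactive", "other")))
    p_dmv <- config$p_dmv[group]
    dmv <- stats::runif(n) < p_dmv
    p_hmr <- c(always_prcs5p = 1, to_prc_only = 0.5, to_inactive = 0.08,
               other = 0.3)[group]
    small_hmr <- !dmv & stats::runif(n) < p_hmr
    truth$dmv_member <- dmv

    tss <- genes$tss
    hmr <- rbind(
      data.frame(chrom = rep(genes$chrom[dmv], each = 3),
                 start = as.vector(vapply(tss[dmv], function(x)
                   c(x - 4000, x - 1000, x + 2000), numeric(3))),
                 end = as.vector(vapply(tss[dmv], function(x)
                   c(x - 1500, x + 1500, x + 4000), numeric(3)))),
      data.frame(chrom = genes$chrom[small_hmr],
                 start = tss[small_hmr] - 750, end = tss[small_hmr] + 750)
    )
    hmr$start <- pmax(0, as.integer(hmr$start)); hmr$end <- as.integer(hmr$end)
    hmr <- hmr[order(hmr$chrom, hmr$start), , drop = FALSE]
    rownames(hmr) <- NULL

    p_cgi <- c(always_prcs5p = 0.95, to_prc_only = 0.6, to_inactive = 0.3,
               other = 0.4)[group]
    w_cgi <- ifelse(group == "always_prcs5p",
                    stats::runif(n, 1200, 2500),
                    stats::runif(n, 200, 800))
    has_cgi <- stats::runif(n) < p_cgi
    cgi <- data.frame(chrom = genes$chrom[has_cgi],
                      start = pmax(0, as.integer(tss[has_cgi] - w_cgi[has_cgi] / 2)),
                      end = as.integer(tss[has_cgi] + w_cgi[has_cgi] / 2),
                      stringsAsFactors = FALSE)
    cgi <- cgi[order(cgi$chrom, cgi$start), , drop = FALSE]
    rownames(cgi) <- NULL

    # TF panel: up to n_tf_per_state genes per day-30 promoter state
    d30 <- truth$state_day30
    panel <- do.call(rbind, lapply(unique(d30), function(s) {
      cand <- truth$gene[d30 == s]
      sel <- if (length(cand) > config$n_tf_per_state)
        sort(sample(cand, config$n_tf_per_state)) else sort(cand)
      data.frame(tf = sel, day30_state = s, stringsAsFactors = FALSE)
    }))
    panel$planted_poised <-
      truth$archetype[match(panel$tf, truth$gene)] == "always_prcs5p"
    n_tf <- nrow(panel)
    conversions <- sprintf("conversion_%02d", seq_len(config$n_conversions))
    tf_ranks <- do.call(rbind, lapply(conversions, function(cv) {
      latent <- stats::rnorm(n_tf) + config$rank_bias * panel$planted_poised
      data.frame(tf = panel$tf, conversion = cv,
                 rank = rank(-latent, ties.method = "first"),
                 stringsAsFactors = FALSE)
    }))
    rownames(tf_ranks) <- NULL

    list(cgi = cgi, hmr = hmr, tf_ranks = tf_ranks, tf_panel = panel,
         truth = truth)
  })
}

#' Simulate the full synthetic cohort
#'
#' Runs all generator stages under a single seed (each stage on its own
#' derived stream, so stages can be regenerated independently) and returns
#' every input the pipeline consumes plus the planted truth.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; all derived seeds stay below 2^31.
#' @return list with `truth`, `annotation` (isoforms + s5p_isoform_counts),
#'   `genes`, `regions`, `counts`, `tpm`, `ko`, `cgi`, `hmr`, `tf_ranks`,
#'   `tf_panel`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  seed <- as.integer(seed)
  ann <- generate_annotation(config, seed = (seed * 7L + 1L) %% 2147483647L)
  genes <- ann$genes

  arch_real <- with_seed((seed * 7L + 2L) %% 2147483647L,
                         sample(assign_archetypes(config)))
  # companion genes (if any) are always-active so the filters have marks to act on
  archetype <- c(arch_real, rep("always_active", sum(genes$companion)))
  truth <- data.frame(gene = genes$gene, archetype = archetype,
                      stringsAsFactors = FALSE)
  st <- ARCHETYPE_STATES[truth$archetype, , drop = FALSE]
  for (tp in TIMEPOINTS) truth[[paste0("state_", tp)]] <- unname(st[, tp])

  marks <- generate_mark_data(truth, genes, config,
                              seed = (seed * 7L + 3L) %% 2147483647L)
  expr <- generate_expression(truth, config,
                              seed = (seed * 7L + 4L) %% 2147483647L)
  truth <- expr$truth
  tracks <- generate_tracks_and_ranks(truth, genes, config,
                                      seed = (seed * 7L + 5L) %% 2147483647L)
  truth <- tracks$truth

  list(truth = truth,
       annotation = list(isoforms = ann$isoforms,
                         s5p_isoform_counts = ann$s5p_isoform_counts),
       genes = genes,
       regions = marks$regions, counts = marks$counts,
       tpm = expr$tpm, ko = expr$ko,
       cgi = tracks$cgi, hmr = tracks$hmr,
       tf_ranks = tracks$tf_ranks, tf_panel = tracks$tf_panel,
       config = config, seed = seed)
}

#' Write a simulated cohort to disk
#'
#' Writes exactly the plain-text formats the pipeline readers consume:
#' isoform and count TSVs, per-mark/time point BED3 enriched regions, TPM and
#' knockout TSVs, CGI/HMR BEDs, TF rank TSVs and the planted-truth TSV.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "regions"), recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(cohort$annotation$isoforms, file.path(dir, "isoforms.tsv"))
  write_tsv_table(cohort$annotation$s5p_isoform_counts,
                  file.path(dir, "s5p_isoform_counts.tsv"))
  write_tsv_table(cohort$counts, file.path(dir, "counts.tsv"))
  for (m in names(cohort$regions)) for (tp in names(cohort$regions[[m]])) {
    write_bed3(cohort$regions[[m]][[tp]],
               file.path(dir, "regions", paste0(m, "_", tp, ".bed")))
  }
  tpm <- data.frame(gene = rownames(cohort$tpm), cohort$tpm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(tpm, file.path(dir, "tpm.tsv"))
  write_tsv_table(cohort$ko, file.path(dir, "ko.tsv"))
  write_bed3(cohort$cgi, file.path(dir, "cgi.bed"))
  write_bed3(cohort$hmr, file.path(dir, "hmr.bed"))
  write_tsv_table(cohort$tf_ranks, file.path(dir, "tf_ranks.tsv"))
  write_tsv_table(cohort$tf_panel, file.path(dir, "tf_panel.tsv"))
  write_tsv_table(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list mirroring [simulate_cohort()] output (without `config`).
#' @export
read_cohort <- function(dir) {
  need <- c("isoforms.tsv", "s5p_isoform_counts.tsv", "counts.tsv",
            "tpm.tsv", "ko.tsv", "cgi.bed", "hmr.bed", "tf_ranks.tsv",
            "tf_panel.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  regions <- stats::setNames(vector("list", length(MARKS)), MARKS)
  for (m in MARKS) {
    regions[[m]] <- stats::setNames(vector("list", length(TIMEPOINTS)),
                                    TIMEPOINTS)
    for (tp in TIMEPOINTS) {
      f <- file.path(dir, "regions", paste0(m, "_", tp, ".bed"))
      if (!file.exists(f)) missing <- c(missing, file.path("regions", basename(f)))
      else regions[[m]][[tp]] <- read_bed3(f)
    }
  }
  if (length(missing) > 0) {
    stop("cohort directory ", dir, " is missing: ",
         paste(missing, collapse = ", "))
  }
  tpm_df <- read_tsv_table(file.path(dir, "tpm.tsv"))
  tpm <- as.matrix(tpm_df[, -1, drop = FALSE])
  rownames(tpm) <- tpm_df$gene
  truth_path <- file.path(dir, "truth.tsv")
  list(
    annotation = list(
      isoforms = read_isoform_table(file.path(dir, "isoforms.tsv")),
      s5p_isoform_counts = read_tsv_table(file.path(dir, "s5p_isoform_counts.tsv"))
    ),
    counts = read_tsv_table(file.path(dir, "counts.tsv")),
    regions = regions,
    tpm = tpm,
    ko = read_tsv_table(file.path(dir, "ko.tsv")),
    cgi = read_bed3(file.path(dir, "cgi.bed")),
    hmr = read_bed3(file.path(dir, "hmr.bed")),
    tf_ranks = read_tsv_table(file.path(dir, "tf_ranks.tsv")),
    tf_panel = read_tsv_table(file.path(dir, "tf_panel.tsv")),
    truth = if (file.exists(truth_path)) read_tsv_table(truth_path) else NULL
  )
}
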