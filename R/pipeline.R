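# End-to-end orchestration: annotate -> classify -> dynamics ->
# expression / features / enrichment, with a JSON run manifest.

#' Run the full promoter-state pipeline on a cohort directory
#'
#' Executes the stages in dependency order on the files of a cohort directory
#' (see [write_cohort()] for the layout), writes one TSV per stage under
#' `out_dir`, and returns (and writes) a run manifest recording the seed, a
#' hash of the configuration, every consumed and produced file, and per-stage
#' gene counts. Any missing input aborts before stage execution, naming the
#' missing piece; per-state counts are checked to sum to the analysis-set
#' size.
#'
#' @param config list (or path to a YAML file) with elements `input_dir`,
#'   `out_dir`, `seed` (isoform-selection seed, default 1) and optional
#'   overrides `inclusive`, `min_overlap`, `remove`, `hmr_max_gap`,
#'   `dmv_min_length`, `n_permutations`.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  config_path <- NULL
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  stopifnot(!is.null(config$input_dir), !is.null(config$out_dir))
  defaults <- list(seed = 1L, inclusive = FALSE, min_overlap = 200L,
                   remove = "both", hmr_max_gap = 1000L,
                   dmv_min_length = 5000L, n_permutations = 1000L)
  config <- utils::modifyList(defaults, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_info <- function(...) message("[promoterstates] ", sprintf(...))
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv_table(df, path)
    outputs[[name]] <<- path
    path
  }

  cohort <- read_cohort(config$input_dir)  # aborts naming anything missing

  log_info("annotation: %d isoform rows", nrow(cohort$annotation$isoforms))
  iso <- filter_clusters(cohort$annotation$isoforms)
  annotation <- build_nonredundant(iso, cohort$annotation$s5p_isoform_counts,
                                   seed = config$seed)
  emit(annotation, "nonredundant_genes.tsv")

  log_info("classification: %d clusters x %d time points",
           length(unique(annotation$cluster_id)), length(TIMEPOINTS))
  cls <- classify_cohort(annotation, cohort$regions, cohort$counts,
                         inclusive = config$inclusive,
                         min_overlap = config$min_overlap,
                         remove = config$remove)
  emit(cls$states, "promoter_states.tsv")
  emit(cls$thresholds, "thresholds.tsv")
  log_info("analysis set: %d of %d genes (NA-excluded: %d)",
           length(cls$analysis_set), nrow(cls$state_matrix),
           nrow(cls$state_matrix) - length(cls$analysis_set))

  sm <- cls$state_matrix[cls$analysis_set, , drop = FALSE]
  k27 <- matrix(STATE_FLAGS[sm, "H3K27me3"], nrow = nrow(sm),
                dimnames = dimnames(sm))
  groups <- prc_dynamics(k27)
  acq <- transient_acquisition(k27, groups)
  fates <- prcs5p_fates(sm)
  dyn <- data.frame(gene = rownames(sm), dynamics_group = as.character(groups),
                    stringsAsFactors = FALSE)
  dyn$first_acquired <- acq$first_acquired[match(dyn$gene, acq$gene)]
  dyn$transient <- acq$transient[match(dyn$gene, acq$gene)]
  dyn$prcs5p_fate <- fates$fates$fate[match(dyn$gene, fates$fates$gene)]
  emit(dyn, "dynamics.tsv")
  tm <- transition_matrix(sm[, 1], sm[, ncol(sm)])
  emit(data.frame(from = rownames(tm), as.data.frame.matrix(tm),
                  check.names = FALSE), "transitions_ESC_day30.tsv")

  tpm <- cohort$tpm[rownames(cohort$tpm) %in% rownames(sm), , drop = FALSE]
  peaking <- select_peaking_genes(tpm)
  emit(peaking, "peaking_genes.tsv")
  esc_states <- stats::setNames(sm[, 1], rownames(sm))
  ko <- cohort$ko[cohort$ko$gene %in% rownames(sm), ]
  upreg <- per_state_upregulation(esc_states,
                                  stats::setNames(ko$wt_expr, ko$gene),
                                  stats::setNames(ko$ko_expr, ko$gene))
  emit(upreg, "ko_upregulation.tsv")

  ann30 <- annotation[annotation$timepoint == "day30", ]
  ann30 <- ann30[ann30$cluster_id %in% rownames(sm), ]
  win30 <- data.frame(gene = ann30$cluster_id, chrom = ann30$chrom,
                      start = ann30$tss_start, end = ann30$tss_end,
                      stringsAsFactors = FALSE)
  merged <- cluster_hmrs(cohort$hmr, max_gap = config$hmr_max_gap)
  dmvs <- define_dmvs(merged, min_length = config$dmv_min_length)
  feats <- data.frame(
    gene = win30$gene,
    k27_breadth_day30 = h3k27me3_breadth(win30, cohort$regions$H3K27me3$day30),
    cgi_tss = cgi_coverage(win30, cohort$cgi),
    methylation = promoter_methylation_class(win30, dmvs, cohort$hmr),
    stringsAsFactors = FALSE
  )
  emit(feats, "promoter_features.tsv")
  emit(dmvs, "dmvs.tsv")

  mean_ranks <- average_influence_rank(cohort$tf_ranks)
  scores <- rank_to_score(stats::setNames(mean_ranks$mean_rank, mean_ranks$tf))
  tf_states <- stats::setNames(cohort$tf_panel$day30_state, cohort$tf_panel$tf)
  sets <- split(names(tf_states), tf_states)
  sets <- sets[lengths(sets) > 0 & lengths(sets) < length(scores)]
  gsea <- gsea_preranked_sets(scores, sets,
                              n_permutations = config$n_permutations,
                              seed = config$seed)
  emit(gsea, "tf_state_gsea.tsv")
  hyper <- do.call(rbind, lapply(names(sets), function(s) {
    top <- names(sort(scores, decreasing = TRUE))[seq_len(min(50, length(scores)))]
    cbind(state = s, hypergeom_state_enrichment(top, sets[[s]], names(scores)))
  }))
  emit(hyper, "tf_state_hypergeom.tsv")

  state_counts <- apply(sm, 2, function(x) table(factor(x, PROMOTER_STATES)))
  if (!all(colSums(state_counts) == length(cls$analysis_set))) {
    stop("manifest inconsistency: per-state counts do not sum to analysis set")
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    inputs = list(input_dir = config$input_dir),
    outputs = as.list(outputs),
    counts = list(
      n_genes = nrow(cls$state_matrix),
      n_analysis_set = length(cls$analysis_set),
      n_na_excluded = nrow(cls$state_matrix) - length(cls$analysis_set),
      per_state = apply(state_counts, 2, as.list),
      dynamics = as.list(table(groups))
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_info("pipeline complete: manifest at %s",
           file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
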