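# Shared fixtures: cached synthetic cohorts and their classification, so the
# expensive pieces are built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

test_cohort <- function(seed = 11, n_genes = 400, ...) {
  key <- paste("cohort", seed, n_genes, deparse(substitute(list(...))),
               collapse = "_")
  cached(key, simulate_cohort(sim_config(n_genes = n_genes, ...), seed = seed))
}

classify_test_cohort <- function(co, seed = 1) {
  iso <- filter_clusters(co$annotation$isoforms)
  ann <- build_nonredundant(iso, co$annotation$s5p_isoform_counts, seed = seed)
  cls <- classify_cohort(ann, co$regions, co$counts)
  list(annotation = ann, cls = cls)
}

planted_states <- function(co, genes) {
  as.matrix(co$truth[match(genes, co$truth$gene),
                     paste0("state_", TIMEPOINTS)])
}

k27_flags <- function(state_matrix) {
  matrix(state_matrix %in% c("PRC_S5p", "PRC_Only", "PRC_Active", "PRC_S7p"),
         nrow = nrow(state_matrix), dimnames = dimnames(state_matrix))
}
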