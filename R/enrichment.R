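# Hypergeometric enrichment of promoter states in gene lists, TF influence
# rank aggregation and human-mouse homolog matching.

#' Hypergeometric enrichment/depletion of a promoter state in a gene list
#'
#' Given a gene universe, a promoter-state gene set and a query list (for
#' example, transcription factors predicted to drive a cell conversion), tests
#' whether the list over- or under-represents the state under the
#' hypergeometric model: `p_enrich = P(X >= overlap)` and
#' `p_deplete = P(X <= overlap)`. Both one-sided p-values are reported and no
#' multiple-testing correction is applied.
#'
#' @param list_genes,state_genes character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return data.frame with `universe_size`, `set_size`, `list_size`,
#'   `overlap`, `p_enrich`, `p_deplete`.
#' @export
hypergeom_state_enrichment <- function(list_genes, state_genes, universe) {
  list_genes <- unique(list_genes)
  state_genes <- unique(state_genes)
  universe <- unique(universe)
  if (!all(list_genes %in% universe)) stop("gene list not contained in universe")
  if (!all(state_genes %in% universe)) stop("state set not contained in universe")
  N <- length(universe)
  K <- length(state_genes)
  n <- length(list_genes)
  k <- length(intersect(list_genes, state_genes))
  data.frame(
    universe_size = N, set_size = K, list_size = n, overlap = k,
    p_enrich = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_deplete = stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  )
}

#' Average influence rank of a transcription factor
#'
#' The mean of a TF's per-conversion influence ranks (lower = more
#' influential) over every conversion in which it is ranked.
#'
#' @param ranks numeric vector of per-conversion ranks (named by conversion),
#'   or a data.frame with columns `tf`, `conversion`, `rank` to aggregate for
#'   all TFs at once.
#' @return scalar mean rank, or a data.frame `tf`, `mean_rank`,
#'   `n_conversions` when a table is given.
#' @export
average_influence_rank <- function(ranks) {
  if (is.data.frame(ranks)) {
    stopifnot(all(c("tf", "conversion", "rank") %in% names(ranks)))
    if (nrow(ranks) == 0) stop("no conversions supplied")
    agg <- tapply(ranks$rank, ranks$tf, mean)
    nn <- tapply(ranks$rank, ranks$tf, length)
    out <- data.frame(tf = names(agg), mean_rank = as.numeric(agg),
                      n_conversions = as.integer(nn),
                      row.names = NULL, stringsAsFactors = FALSE)
    return(out[order(out$tf), , drop = FALSE])
  }
  if (length(ranks) == 0) stop("no conversions supplied")
  mean(ranks)
}

#' Influence ranks to GSEA ranking scores
#'
#' Converts mean influence ranks (lower = more influential) into decreasing
#' ranking scores, `max_rank - rank + 1`, so high-influence TFs sit at the top
#' of the ranked list.
#'
#' @param mean_ranks named numeric vector of mean ranks.
#' @param max_rank maximum possible rank; defaults to the number of TFs.
#' @return named numeric vector of scores.
#' @export
rank_to_score <- function(mean_ranks, max_rank = length(mean_ranks)) {
  stopifnot(!is.null(names(mean_ranks)))
  max_rank - mean_ranks + 1
}

#' Match human genes to mouse homologs
#'
#' Keeps genes with exactly one mouse homolog in the table; genes with no
#' match or with ambiguous (more than one) matches are dropped and counted.
#' Matching is by exact gene name.
#'
#' @param human_genes character vector of human gene names.
#' @param homology_table data.frame with columns `human_name`, `mouse_name`.
#' @return data.frame `human_name`, `mouse_name` for the 1:1 matches;
#'   attributes `n_unmatched` and `n_ambiguous`.
#' @export
match_homologs <- function(human_genes, homology_table) {
  stopifnot(all(c("human_name", "mouse_name") %in% names(homology_table)))
  human_genes <- unique(human_genes)
  sub <- unique(homology_table[homology_table$human_name %in% human_genes,
                               c("human_name", "mouse_name"), drop = FALSE])
  n_per_gene <- table(sub$human_name)
  ambiguous <- names(n_per_gene)[n_per_gene > 1]
  unmatched <- setdiff(human_genes, sub$human_name)
  keep <- sub[!(sub$human_name %in% ambiguous), , drop = FALSE]
  keep <- keep[order(keep$human_name), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_unmatched") <- length(unmatched)
  attr(keep, "n_ambiguous") <- length(ambiguous)
  keep
}
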