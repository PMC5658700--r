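# Temporal trajectory groups: Polycomb Maintained/Lost/Acquired, transient
# acquisition, and the fates of ESC PRC/S5p promoters.

#' Polycomb dynamics groups from H3K27me3 trajectories
#'
#' Partition of genes by H3K27me3 positivity over the ordered time course:
#' \describe{
#'   \item{Maintained}{positive at all five time points.}
#'   \item{Lost}{positive at the first time point but not at all five (genes
#'     that lose and later regain the mark count as Lost unless regained at
#'     every time point; this is the reading under which Maintained + Lost
#'     equals the first-time-point positive count).}
#'   \item{Acquired}{negative at the first time point, positive at one or more
#'     later points.}
#'   \item{NeverPRC}{negative everywhere.}
#' }
#'
#' @param k27 logical matrix, genes x time points (H3K27me3 positivity), no
#'   `NA`s.
#' @return factor of group labels, named by gene.
#' @export
prc_dynamics <- function(k27) {
  stopifnot(is.matrix(k27), is.logical(k27), ncol(k27) >= 2)
  if (anyNA(k27)) stop("NA in H3K27me3 trajectory: exclude NA genes first")
  all_pos <- rowSums(k27) == ncol(k27)
  esc_pos <- k27[, 1]
  any_later <- rowSums(k27[, -1, drop = FALSE]) > 0
  lab <- ifelse(all_pos, "Maintained",
                ifelse(esc_pos, "Lost",
                       ifelse(any_later, "Acquired", "NeverPRC")))
  factor(stats::setNames(lab, rownames(k27)),
         levels = c("Maintained", "Lost", "Acquired", "NeverPRC"))
}

#' Timing and persistence of de novo H3K27me3 acquisition
#'
#' For the Acquired genes, records the time point of first acquisition and
#' whether the mark is transient (negative again at some later time point) or
#' retained.
#'
#' @param k27 logical matrix, genes x time points.
#' @param groups optional precomputed [prc_dynamics()] output.
#' @return data.frame `gene`, `first_acquired`, `transient`.
#' @export
transient_acquisition <- function(k27, groups = prc_dynamics(k27)) {
  acq <- names(groups)[groups == "Acquired"]
  if (length(acq) == 0) {
    return(data.frame(gene = character(), first_acquired = character(),
                      transient = logical()))
  }
  sub <- k27[acq, , drop = FALSE]
  first_idx <- apply(sub, 1, function(x) which(x)[1])
  transient <- vapply(seq_along(acq), function(i) {
    later <- sub[i, -seq_len(first_idx[i]), drop = TRUE]
    length(later) > 0 && any(!later)
  }, logical(1))
  data.frame(gene = acq,
             first_acquired = colnames(k27)[first_idx],
             transient = transient,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fates of promoters poised (PRC/S5p) in ESCs
#'
#' For genes whose first-time-point state is PRC_S5p, reports the final-time-
#' point state (collapsed to Active, PRC_Active, PRC_S5p, PRC_Only, Inactive,
#' or "other") and the stricter "Always PRC/S5p" flag (PRC_S5p at every time
#' point). Also returns the three silent-fate membership lists: Always
#' PRC/S5p, resolving to PRC Only, and resolving to Inactive.
#'
#' @param states character matrix, genes x time points, of promoter states
#'   (no `NA` rows).
#' @return list with `fates` (data.frame `gene`, `day30_state`, `fate`,
#'   `always_prcs5p`) and `groups` (list of gene-id vectors
#'   `always_prcs5p`, `to_prc_only`, `to_inactive`).
#' @export
prcs5p_fates <- function(states) {
  stopifnot(is.matrix(states), ncol(states) >= 2)
  esc <- states[, 1] == "PRC_S5p"
  esc[is.na(esc)] <- FALSE
  sub <- states[esc, , drop = FALSE]
  final <- sub[, ncol(sub)]
  fate_levels <- c("Active", "PRC_Active", "PRC_S5p", "PRC_Only", "Inactive")
  fate <- ifelse(final %in% fate_levels, final, "other")
  always <- rowSums(sub == "PRC_S5p", na.rm = TRUE) == ncol(sub)
  fates <- data.frame(gene = rownames(sub), day30_state = final, fate = fate,
                      always_prcs5p = always,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(fates = fates,
       groups = list(
         always_prcs5p = fates$gene[fates$always_prcs5p],
         to_prc_only = fates$gene[fates$fate == "PRC_Only"],
         to_inactive = fates$gene[fates$fate == "Inactive"]
       ))
}

#' Promoter-state transition matrix between two time points
#'
#' @param states_a,states_b character vectors of states for the same genes
#'   (same order and names); `NA` states are tabulated in an explicit NA row/
#'   column.
#' @return 9 x 9 integer matrix (8 states + NA) of gene counts; the total
#'   equals the number of genes.
#' @export
transition_matrix <- function(states_a, states_b) {
  if (length(states_a) != length(states_b)) {
    stop("state vectors cover different gene universes")
  }
  if (!is.null(names(states_a)) && !is.null(names(states_b)) &&
      !identical(names(states_a), names(states_b))) {
    stop("state vectors cover different gene universes")
  }
  lv <- c(PROMOTER_STATES, NA)
  fa <- factor(states_a, levels = PROMOTER_STATES)
  fb <- factor(states_b, levels = PROMOTER_STATES)
  m <- table(addNA(fa, ifany = FALSE), addNA(fb, ifany = FALSE))
  m <- unclass(m)
  dimnames(m) <- list(from = c(PROMOTER_STATES, "NA"),
                      to = c(PROMOTER_STATES, "NA"))
  m
}
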