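# Expression dynamics (z-score peaking), pseudo-counted log-TPM, and
# Polycomb-knockout derepression calls.

#' Row-wise z-score standardization of a TPM matrix
#'
#' Each row is centered on its mean and divided by its sample standard
#' deviation (n - 1 denominator, `sd_type = "sample"`; set `"population"` for
#' the n denominator). Constant rows are returned as all zeros and flagged
#' degenerate.
#'
#' @param tpm numeric matrix, genes x time points.
#' @param sd_type "sample" (default) or "population".
#' @return matrix of z-scores with logical attribute `degenerate` (per row).
#' @export
zscore_standardize <- function(tpm, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.matrix(tpm), ncol(tpm) >= 2)
  mu <- rowMeans(tpm)
  dev <- tpm - mu
  denom <- if (sd_type == "sample") ncol(tpm) - 1 else ncol(tpm)
  sdv <- sqrt(rowSums(dev^2) / denom)
  degenerate <- sdv == 0
  sdv[degenerate] <- 1
  z <- dev / sdv
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- degenerate
  z
}

#' Select genes whose expression peaks in a single time point
#'
#' A gene is selected when its standardized expression exceeds `z_threshold`
#' in exactly one time point and it is expressed above `expr_threshold` TPM in
#' at least one time point. The peak is the arg-max z time point. Genes
#' exceeding the z cut at two or more time points are not single-time-point
#' peaks and are excluded, as are constant (degenerate) rows.
#'
#' @param tpm numeric matrix, genes x time points (column names = labels).
#' @param z_threshold z-score cut, default 1.75.
#' @param expr_threshold TPM expression requirement, default 1.
#' @param sd_type passed to [zscore_standardize()].
#' @return data.frame `gene`, `peak_timepoint`, `max_z` for selected genes.
#' @export
select_peaking_genes <- function(tpm, z_threshold = 1.75, expr_threshold = 1,
                                 sd_type = "sample") {
  z <- zscore_standardize(tpm, sd_type = sd_type)
  n_above <- rowSums(z > z_threshold)
  expressed <- apply(tpm, 1, max) > expr_threshold
  sel <- n_above == 1 & expressed & !attr(z, "degenerate")
  peak_idx <- max.col(z, ties.method = "first")
  data.frame(gene = rownames(tpm)[sel],
             peak_timepoint = colnames(tpm)[peak_idx[sel]],
             max_z = z[cbind(which(sel), peak_idx[sel])],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pseudo-counted log10 TPM
#'
#' `log10(tpm + 1e-4)`; 0 TPM maps to -4.
#'
#' @param tpm non-negative numeric vector.
#' @param pseudo pseudo-count, default `1e-4`.
#' @return numeric vector.
#' @export
log_tpm <- function(tpm, pseudo = 1e-4) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  log10(tpm + pseudo)
}

#' Call genes upregulated in a Polycomb knockout
#'
#' Fold change is knockout over wild-type expression, with the wild-type value
#' floored at a small epsilon so silent-WT genes still yield a finite (large)
#' fold change. A gene is upregulated when FC > `fc_threshold` and the
#' knockout expression exceeds `ko_expr_threshold` (FPKM).
#'
#' @param wt,ko non-negative expression values (FPKM), replicate-averaged.
#' @param fc_threshold fold-change cut, default 2.
#' @param ko_expr_threshold knockout expression cut, default 1 FPKM.
#' @param eps denominator floor, default 1e-6.
#' @return logical vector.
#' @export
call_upregulated <- function(wt, ko, fc_threshold = 2, ko_expr_threshold = 1,
                             eps = 1e-6) {
  stopifnot(all(wt >= 0), all(ko >= 0))
  fc <- ko / pmax(wt, eps)
  fc > fc_threshold & ko > ko_expr_threshold
}

#' Per-promoter-state knockout upregulation fractions
#'
#' For each promoter state, the fraction of its genes called upregulated in
#' the knockout. Genes in repressed states (PRC_S5p, PRC_Only, Inactive by
#' default) that are already expressed above `wt_expr_threshold` FPKM in the
#' wild type are unlikely to carry a truly repressed promoter and are removed
#' from both numerator and denominator. Gene universes are intersected by
#' exact identifier match; unmatched genes are dropped and counted.
#'
#' @param states named character vector: promoter state per gene.
#' @param wt,ko named numeric vectors of wild-type / knockout expression.
#' @param repressed_states states subject to the wild-type expression
#'   exclusion.
#' @param wt_expr_threshold FPKM cut for the exclusion, default 1.
#' @param ... passed to [call_upregulated()].
#' @return data.frame `state`, `n`, `n_up`, `fraction` (NA and flagged when a
#'   state has an empty denominator); attributes `n_unmatched` and
#'   `n_excluded_wt`.
#' @export
per_state_upregulation <- function(states, wt, ko,
                                   repressed_states = c("PRC_S5p", "PRC_Only",
                                                        "Inactive"),
                                   wt_expr_threshold = 1, ...) {
  common <- intersect(names(states), intersect(names(wt), names(ko)))
  n_unmatched <- length(states) - length(common)
  st <- states[common]
  wt <- wt[common]
  ko <- ko[common]
  excl <- st %in% repressed_states & wt > wt_expr_threshold
  st <- st[!excl]; wt <- wt[!excl]; ko <- ko[!excl]
  up <- call_upregulated(wt, ko, ...)
  levels <- unique(c(intersect(PROMOTER_STATES, st), setdiff(st, PROMOTER_STATES)))
  out <- do.call(rbind, lapply(levels, function(s) {
    i <- st == s
    data.frame(state = s, n = sum(i), n_up = sum(up[i]),
               fraction = if (sum(i) > 0) sum(up[i]) / sum(i) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "n_excluded_wt") <- sum(excl)
  out
}
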