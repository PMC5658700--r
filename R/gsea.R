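# Preranked gene-set enrichment statistic: weighted Kolmogorov-Smirnov-like
# running sum, gene-label permutation null, NES and FDR.

#' Running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing by
#' `|score|^p / sum(|score_hits|^p)` at gene-set members and decrementing by
#' `1 / (N - n_set)` at non-members; the enrichment score is the running sum's
#' signed maximum deviation from zero.
#'
#' @param scores numeric vector of ranking scores, sorted decreasing.
#' @param hits logical vector marking gene-set members, parallel to `scores`.
#' @param weight_exponent weight `p`; 1 is the classic weighted statistic, 0
#'   gives the unweighted Kolmogorov-Smirnov form.
#' @return list with `es` and the full `running` sum.
#' @keywords internal
gsea_running_sum <- function(scores, hits, weight_exponent = 1) {
  n <- length(scores)
  nh <- sum(hits)
  stopifnot(nh > 0, nh < n)
  w <- abs(scores)^weight_exponent
  nr <- sum(w[hits])
  if (nr == 0) stop("all hit weights are zero; cannot normalize running sum")
  inc <- ifelse(hits, w / nr, -1 / (n - nh))
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Preranked gene-set enrichment test
#'
#' Computes the enrichment score of `gene_set` on a ranked gene list, a
#' gene-label permutation null (the only null available for preranked input),
#' a normalized enrichment score (ES divided by the mean absolute null ES of
#' the same sign), and a permutation p-value. With a single gene set the
#' reported `fdr` equals the permutation p-value; use
#' [gsea_preranked_sets()] for the pooled multi-set FDR.
#'
#' A positive ES means concentration at the top of the ranking (high scores);
#' ties in `scores` are broken by stable identifier order.
#'
#' @param scores named numeric vector of ranking scores (higher = nearer the
#'   top); need not be pre-sorted.
#' @param gene_set character vector of gene identifiers; must be a subset of
#'   `names(scores)` and smaller than the list.
#' @param weight_exponent weight `p`, default 1.
#' @param n_permutations number of gene-label permutations, default 1000
#'   (minimum 100).
#' @param seed integer RNG seed for the permutation null.
#' @return object of class `gsea_result`: list with `es`, `nes`, `p_value`,
#'   `fdr`, `direction` ("top" or "bottom"), `n_permutations`, `seed`,
#'   `set_size`, `list_size`, `null_es`.
#' @export
gsea_preranked <- function(scores, gene_set, weight_exponent = 1,
                           n_permutations = 1000L, seed = 1L) {
  prep <- gsea_prepare(scores, list(set = gene_set))
  null_es <- gsea_null(prep$scores, length(prep$hit_idx[[1]]), weight_exponent,
                       n_permutations, seed)
  obs <- gsea_running_sum(prep$scores,
                          seq_along(prep$scores) %in% prep$hit_idx[[1]],
                          weight_exponent)
  res <- gsea_normalize(obs$es, null_es)
  structure(list(es = obs$es, nes = res$nes, p_value = res$p,
                 fdr = res$p, direction = if (obs$es >= 0) "top" else "bottom",
                 n_permutations = n_permutations, seed = seed,
                 set_size = length(prep$hit_idx[[1]]),
                 list_size = length(prep$scores),
                 null_es = null_es),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "Preranked GSEA: ES = %.3f (%s of ranking), NES = %.3f, p = %.4g, FDR = %.4g\n",
    x$es, x$direction, x$nes, x$p_value, x$fdr))
  cat(sprintf("  set %d / list %d, %d permutations (seed %d)\n",
              x$set_size, x$list_size, x$n_permutations, x$seed))
  invisible(x)
}

#' Preranked GSEA over several gene sets with pooled FDR
#'
#' Runs the running-sum statistic for each set against a shared gene-label
#' permutation null and estimates the false discovery rate with the standard
#' positive/negative-pool procedure: for a set with normalized score NES*,
#' the FDR is the fraction of pooled null NES at least as extreme (same sign)
#' divided by the fraction of observed NES at least as extreme, clipped to
#' [0, 1].
#'
#' @param scores named numeric vector of ranking scores.
#' @param gene_sets named list of gene-id vectors.
#' @inheritParams gsea_preranked
#' @return data.frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p_value`, `fdr`, `direction`.
#' @export
gsea_preranked_sets <- function(scores, gene_sets, weight_exponent = 1,
                                n_permutations = 1000L, seed = 1L) {
  prep <- gsea_prepare(scores, gene_sets)
  sizes <- lengths(prep$hit_idx)
  # one permutation null per distinct set size, shared across sets
  nulls <- lapply(stats::setNames(unique(sizes), unique(sizes)), function(k) {
    gsea_null(prep$scores, k, weight_exponent, n_permutations,
              seed + as.integer(k))
  })
  obs_es <- vapply(prep$hit_idx, function(idx) {
    gsea_running_sum(prep$scores, seq_along(prep$scores) %in% idx,
                     weight_exponent)$es
  }, numeric(1))
  per_set <- lapply(seq_along(obs_es), function(i) {
    gsea_normalize(obs_es[i], nulls[[as.character(sizes[i])]])
  })
  nes <- vapply(per_set, `[[`, numeric(1), "nes")
  pval <- vapply(per_set, `[[`, numeric(1), "p")
  null_nes <- unlist(lapply(seq_along(obs_es), function(i) {
    gsea_normalize_null(nulls[[as.character(sizes[i])]])
  }), use.names = FALSE)
  fdr <- vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num_pool <- null_nes[null_nes >= 0]
      obs_pool <- nes[!is.na(nes) & nes >= 0]
      num <- mean(num_pool >= x)
      den <- mean(obs_pool >= x)
    } else {
      num_pool <- null_nes[null_nes < 0]
      obs_pool <- nes[!is.na(nes) & nes < 0]
      num <- mean(num_pool <= x)
      den <- mean(obs_pool <= x)
    }
    if (is.nan(num)) num <- 0
    if (is.nan(den) || den == 0) den <- 1 / max(length(obs_pool), 1)
    min(1, num / den)
  }, numeric(1))
  data.frame(set = names(gene_sets), size = as.integer(sizes),
             es = obs_es, nes = nes, p_value = pval, fdr = fdr,
             direction = ifelse(obs_es >= 0, "top", "bottom"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
gsea_prepare <- function(scores, gene_sets) {
  if (is.null(names(scores))) stop("scores must be named by gene identifier")
  # decreasing score; ties broken by stable identifier order
  ord <- order(-scores, names(scores), method = "radix")
  scores <- scores[ord]
  hit_idx <- lapply(gene_sets, function(set) {
    missing <- setdiff(set, names(scores))
    if (length(missing) > 0) {
      stop("gene set member(s) absent from ranked list: ",
           paste(utils::head(missing, 3), collapse = ", "))
    }
    if (length(set) >= length(scores)) {
      stop("gene set as large as the ranked list")
    }
    if (length(set) == 0) stop("empty gene set")
    which(names(scores) %in% set)
  })
  list(scores = scores, hit_idx = hit_idx)
}

#' @keywords internal
gsea_null <- function(scores, set_size, weight_exponent, n_permutations, seed) {
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  n <- length(scores)
  w <- abs(scores)^weight_exponent
  dec <- -1 / (n - set_size)
  with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, set_size)
      inc <- rep(dec, n)
      inc[idx] <- w[idx] / sum(w[idx])
      running <- cumsum(inc)
      running[which.max(abs(running))]
    }, numeric(1))
  })
}

#' @keywords internal
gsea_normalize <- function(es, null_es) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) == 0) {
    return(list(nes = NA_real_, p = 1 / (1 + length(null_es))))
  }
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p = p)
}

#' @keywords internal
gsea_normalize_null <- function(null_es) {
  pos <- null_es[null_es >= 0]
  neg <- null_es[null_es < 0]
  out <- null_es
  if (length(pos) > 0) out[null_es >= 0] <- pos / mean(abs(pos))
  if (length(neg) > 0) out[null_es < 0] <- neg / mean(abs(neg))
  out
}
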