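# Independent brute-force oracles. These deliberately use plain loops and
# first-principles arithmetic, never the package's interval/statistics code.

# linear-interpolation quantile by sort-and-index
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# quadratic pairwise exclusion-filter checker on one mark/time point
oracle_exclusion <- function(status, windows, bodies, min_overlap = 200) {
  n <- length(status)
  out <- status
  pos <- which(!is.na(status) & status == "positive")
  drop <- rep(FALSE, n)
  for (i in pos) for (j in pos) {
    if (i >= j || windows$chrom[i] != windows$chrom[j]) next
    ov <- min(windows$end[i], windows$end[j]) -
      max(windows$start[i], windows$start[j])
    if (ov > min_overlap) drop[c(i, j)] <- TRUE
  }
  out[drop] <- NA
  pos <- which(!is.na(out) & out == "positive")
  inner <- rep(FALSE, n)
  for (i in pos) for (j in pos) {
    if (i == j || bodies$chrom[i] != bodies$chrom[j]) next
    if (bodies$start[i] >= bodies$start[j] && bodies$end[i] <= bodies$end[j]) {
      inner[i] <- TRUE
    }
  }
  out[inner] <- NA
  out
}

# repeat-until-fixpoint pairwise interval merging (gap <= max_gap)
oracle_merge <- function(df, max_gap) {
  rows <- split(df, seq_len(nrow(df)))
  repeat {
    merged <- FALSE
    for (i in seq_along(rows)) {
      if (merged) break
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= max_gap) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end))
          rows[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# hypergeometric upper/lower tails by direct summation of the pmf
oracle_hyper <- function(N, K, n, k) {
  pmf <- function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n)
  xs <- max(0, n - (N - K)):min(K, n)
  list(enrich = sum(vapply(xs[xs >= k], pmf, numeric(1))),
       deplete = sum(vapply(xs[xs <= k], pmf, numeric(1))))
}

# enrichment score by explicit evaluation of the running sum at every position
oracle_es <- function(scores_sorted, hit, p = 1) {
  n <- length(scores_sorted)
  nr <- sum(abs(scores_sorted[hit])^p)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) abs(scores_sorted[i])^p / nr else -1 / (n - sum(hit))
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# check an ES against the oracle; when the positive and negative extremes of
# the running sum tie in magnitude (to rounding), either sign is valid
expect_es_equal <- function(es, scores_sorted, hit, p = 1) {
  n <- length(scores_sorted)
  nr <- sum(abs(scores_sorted[hit])^p)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) abs(scores_sorted[i])^p / nr else -1 / (n - sum(hit))
    running[i] <- cur
  }
  if (abs(max(running) + min(running)) < 1e-9) {
    expect_equal(abs(es), max(abs(running)))
  } else {
    expect_equal(es, running[which.max(abs(running))])
  }
}
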