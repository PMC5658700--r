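test_that("read-start counting respects half-open windows and matches a scan", {
  reads <- data.frame(chrom = "chr1", pos = c(5L, 10L, 15L))
  win <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  expect_equal(count_reads_in_window(reads, win(0, 20)), 3L)
  expect_equal(count_reads_in_window(reads, win(10, 15)), 1L)
  expect_equal(count_reads_in_window(reads, win(16, 20)), 0L)

  set.seed(42)
  pos <- sample.int(10000, 1000, replace = TRUE) - 1L
  reads <- data.frame(chrom = "chr1", pos = pos)
  wins <- data.frame(chrom = "chr1",
                     start = c(0L, 250L, 9000L), end = c(1000L, 4000L, 10000L))
  got <- count_reads_in_window(reads, wins)
  brute <- vapply(seq_len(nrow(wins)), function(i)
    sum(pos >= wins$start[i] & pos < wins$end[i]), integer(1))
  expect_equal(got, brute)

  expect_warning(
    out <- count_reads_in_window(reads, data.frame(chrom = "chrX", start = 0L,
                                                   end = 100L)),
    "chrX")
  expect_equal(out, 0L)
})

test_that("positivity threshold is the 5th percentile with documented edge cases", {
  expect_equal(positivity_threshold(rep(7, 20)), 7)
  expect_equal(positivity_threshold(42), 42)
  expect_equal(positivity_threshold(1:100), oracle_quantile(1:100, 0.05))
  expect_error(positivity_threshold(numeric()), "no overlapping genes")
})

test_that("positivity needs both region overlap and an above-threshold count", {
  windows <- data.frame(gene = paste0("g", 1:4), chrom = "chr1",
                        start = c(0L, 10000L, 20000L, 30000L),
                        end = c(2000L, 12000L, 22000L, 32000L))
  regions <- data.frame(chrom = "chr1", start = c(500L, 10500L, 20500L),
                        end = c(1500L, 11500L, 21500L))
  counts <- c(g1 = 100, g2 = 100, g3 = 0, g4 = 100)
  calls <- call_marks(windows, regions, counts)
  # threshold = 5th pct of overlapping counts {100, 100, 0} = 10 (type 7)
  expect_equal(attr(calls, "threshold"), oracle_quantile(c(100, 100, 0), 0.05))
  expect_equal(calls$status, c("positive", "positive", "negative", "negative"))
  # g4 has a high count but no overlapping region
  expect_false(calls$overlapped[4])
  # inclusive reading converts an at-threshold count
  counts2 <- c(g1 = 100, g2 = 100, g3 = 100, g4 = 100)
  thr <- oracle_quantile(c(100, 100, 100), 0.05)
  calls2 <- call_marks(windows, regions, counts2, inclusive = TRUE)
  expect_equal(calls2$status[1:3], rep("positive", 3))
  calls3 <- call_marks(windows, regions, counts2, inclusive = FALSE)
  expect_equal(calls3$status[1:3], rep("negative", 3))  # 100 > 100 is false
  expect_equal(attr(calls3, "threshold"), thr)
})

test_that("raising the threshold never converts a negative call to positive", {
  set.seed(99)
  counts <- rnbinom(200, mu = 50, size = 5)
  for (thr in sort(sample(counts, 10))) {
    lo <- counts > thr
    hi <- counts > thr + 5
    expect_true(all(lo | !hi))
  }
})

make_filter_cohort <- function(offsets, bodies_nested = FALSE) {
  # genes spaced 10 kb apart, then companions at the given TSS offsets
  n <- length(offsets)
  host_tss <- seq(10000L, by = 50000L, length.out = n)
  gene <- c(paste0("h", seq_len(n)), paste0("c", seq_len(n)))
  tss <- c(host_tss, host_tss + offsets)
  windows <- data.frame(gene = gene, chrom = "chr1",
                        start = tss - 1000L, end = tss + 1000L)
  bodies <- if (bodies_nested) {
    data.frame(gene = gene, chrom = "chr1",
               start = c(host_tss, host_tss + 500L),
               end = c(host_tss + 8000L, host_tss + 2500L))
  } else {
    data.frame(gene = gene, chrom = "chr1", start = tss, end = tss + 8000L)
  }
  calls <- data.frame(gene = gene, overlapped = TRUE,
                      count = 100, status = "positive",
                      stringsAsFactors = FALSE)
  list(calls = calls, windows = windows, bodies = bodies)
}

test_that("window-overlap filter removes both genes only above 200 bp", {
  # offsets 1500 and 1850 give 500 bp and 150 bp of TSS-window overlap
  fx <- make_filter_cohort(c(1500L, 1850L))
  out <- apply_exclusion_filters(fx$calls, fx$windows, fx$bodies)
  expect_true(all(is.na(out$status[out$gene %in% c("h1", "c1")])))
  expect_equal(out$status[out$gene %in% c("h2", "c2")], rep("positive", 2))
  # exactly 200 bp (offset 1800) is tolerated; 201 bp is not
  fx <- make_filter_cohort(c(1800L, 1799L))
  out <- apply_exclusion_filters(fx$calls, fx$windows, fx$bodies)
  expect_equal(out$status[out$gene %in% c("h1", "c1")], rep("positive", 2))
  expect_true(all(is.na(out$status[out$gene %in% c("h2", "c2")])))
})

test_that("internal-gene filter removes only the nested gene", {
  fx <- make_filter_cohort(c(5000L), bodies_nested = TRUE)  # windows disjoint
  out <- apply_exclusion_filters(fx$calls, fx$windows, fx$bodies)
  expect_equal(out$status[out$gene == "h1"], "positive")
  expect_true(is.na(out$status[out$gene == "c1"]))
})

test_that("remove='lower' keeps the higher-count gene of an overlapping pair", {
  fx <- make_filter_cohort(c(1000L))
  fx$calls$count <- c(500, 10)
  out <- apply_exclusion_filters(fx$calls, fx$windows, fx$bodies,
                                 remove = "lower")
  expect_equal(out$status[out$gene == "h1"], "positive")
  expect_true(is.na(out$status[out$gene == "c1"]))
})

test_that("exclusion filters are idempotent and match the quadratic oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 60
    tss <- cumsum(sample(c(500L, 1500L, 3000L, 30000L), n, replace = TRUE)) + 5000L
    windows <- data.frame(gene = paste0("g", 1:n), chrom = "chr1",
                          start = tss - 1000L, end = tss + 1000L)
    len <- sample(c(1000L, 5000L, 20000L), n, replace = TRUE)
    bodies <- data.frame(gene = windows$gene, chrom = "chr1",
                         start = tss, end = tss + len)
    calls <- data.frame(gene = windows$gene, overlapped = TRUE, count = 100,
                        status = sample(c("positive", "negative"), n, TRUE,
                                        prob = c(0.8, 0.2)),
                        stringsAsFactors = FALSE)
    out <- apply_exclusion_filters(calls, windows, bodies)
    expect_equal(out$status,
                 oracle_exclusion(calls$status, windows, bodies))
    again <- apply_exclusion_filters(out, windows, bodies)
    expect_identical(out$status, again$status)
  }
})

test_that("the eight-state truth table is exhaustive and NA propagates", {
  expect_equal(classify_state("positive", "positive", "negative"), "PRC_S5p")
  expect_equal(classify_state("negative", "positive", "positive"), "Active")
  expect_true(is.na(classify_state(NA, "positive", "positive")))
  states <- c("positive", "negative")
  combos <- expand.grid(k27 = states, s5p = states, s7p = states,
                        stringsAsFactors = FALSE)
  lab <- classify_state(combos$k27, combos$s5p, combos$s7p)
  expect_setequal(lab, PROMOTER_STATES)  # 8 combos partition the 8 states
  expect_error(classify_state("yes", "positive", "negative"), "status")
})

test_that("cohort classification recovers planted states on clean geometry", {
  co <- test_cohort(seed = 11, n_genes = 400)
  fit <- classify_test_cohort(co)
  cls <- fit$cls
  expect_setequal(cls$analysis_set, co$truth$gene)  # clean geometry: no NAs
  sm <- cls$state_matrix[cls$analysis_set, ]
  expect_equal(unname(sm), unname(planted_states(co, rownames(sm))))
})

test_that("genes NA for one mark at one time point leave the analysis set", {
  # two overlapping positive companions (window overlap > 200 bp) go NA for
  # the marks they share, and drop out of the analysis set entirely
  co <- test_cohort(seed = 23, n_genes = 150, overlap_fraction = 0.1,
                    nested_fraction = 0.05)
  fit <- classify_test_cohort(co)
  cls <- fit$cls
  companions <- co$genes$gene[co$genes$companion]
  expect_gt(length(companions), 0)
  na_genes <- setdiff(rownames(cls$state_matrix), cls$analysis_set)
  expect_gt(length(na_genes), 0)
  # every NA-excluded gene has at least one NA state; analysis-set genes none
  expect_true(all(rowSums(is.na(cls$state_matrix[na_genes, , drop = FALSE])) > 0))
  expect_true(all(!is.na(cls$state_matrix[cls$analysis_set, ])))
})

test_that("missing mark/time point combinations abort with their names", {
  co <- test_cohort(seed = 11, n_genes = 120)
  fit <- classify_test_cohort(co)
  regions <- co$regions
  regions$H3K27me3$day16 <- NULL
  expect_error(
    classify_cohort(fit$annotation, regions, co$counts),
    "H3K27me3/day16")
})
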