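test_that("promoter mark breadth takes the longest overlapping region", {
  win <- data.frame(chrom = "chr1", start = 10000L, end = 12000L)
  regions <- data.frame(chrom = "chr1",
                        start = c(9000L, 11500L, 20000L),
                        end = c(12000L, 12300L, 23000L))
  expect_equal(h3k27me3_breadth(win, regions), 3000)
  expect_equal(h3k27me3_breadth(win, regions[3, ]), 0)
  # half-open: a region abutting the window end does not overlap
  expect_equal(h3k27me3_breadth(win, data.frame(chrom = "chr1", start = 12000L,
                                                end = 13000L)), 0)
  expect_equal(h3k27me3_breadth(win, data.frame(chrom = "chr1", start = 11999L,
                                                end = 13000L)), 1001)
})

test_that("GC fraction excludes N from the denominator", {
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ACGN"), 2 / 3)  # one G + one C over three non-N
  expect_equal(gc_fraction("acg"), 2 / 3)
  expect_true(is.na(gc_fraction("NNN")))
  expect_error(gc_fraction(""), "empty")
  expect_error(gc_fraction("ACGU"), "invalid")
})

test_that("CpG-island coverage merges overlapping islands first", {
  win <- data.frame(chrom = "chr1", start = 0L, end = 2000L)
  expect_equal(cgi_coverage(win, data.frame(chrom = "chr1", start = 500L,
                                            end = 1500L)), 0.5)
  overlapping <- data.frame(chrom = "chr1", start = c(0L, 500L),
                            end = c(1000L, 1500L))
  expect_equal(cgi_coverage(win, overlapping), 0.75)
  expect_equal(cgi_coverage(win, overlapping[0, ]), 0)
  # coverage is capped at 1 for an island spanning the window
  expect_equal(cgi_coverage(win, data.frame(chrom = "chr1", start = 0L,
                                            end = 5000L)), 1)
})

test_that("metagene profiles bin coverage 5'-to-3' and drop out-of-range bins", {
  cov <- list(chr1 = rep(1, 20000))
  anchors <- data.frame(chrom = "chr1", pos = 10000L, strand = "+")
  prof <- metagene_profile(cov, anchors, flank = 100L, bin = 10L)
  expect_equal(unname(prof), rep(1, 20))

  cov2 <- list(chr1 = rep(0, 20000))
  cov2$chr1[10001:10010] <- 1  # 0-based [10000, 10010)
  prof2 <- metagene_profile(cov2, anchors, flank = 100L, bin = 10L)
  expect_equal(sum(prof2 == 1), 1)
  expect_equal(unname(prof2[names(prof2) == "0"]), 1)

  # opposite strands with mirrored coverage give identical profiles
  covp <- list(chr1 = rep(0, 20000)); covp$chr1[10001:10050] <- 1
  covm <- list(chr1 = rep(0, 20000)); covm$chr1[9951:10000] <- 1
  pp <- metagene_profile(covp, data.frame(chrom = "chr1", pos = 10000L,
                                          strand = "+"), 100L, 10L)
  pm <- metagene_profile(covm, data.frame(chrom = "chr1", pos = 10000L,
                                          strand = "-"), 100L, 10L)
  expect_equal(unname(pp), unname(pm))

  # anchor near the chromosome start: upstream bins dropped, not zero-filled
  prof3 <- metagene_profile(cov, data.frame(chrom = "chr1", pos = 50L,
                                            strand = "+"), 100L, 10L)
  expect_true(all(is.na(prof3[1:5])))
  expect_equal(unname(prof3[6:20]), rep(1, 15))
})

test_that("HMR proximity clustering merges across gaps up to max_gap", {
  hmrs <- data.frame(chrom = "chr1", start = c(0L, 3400L), end = c(3000L, 6400L))
  out <- cluster_hmrs(hmrs, max_gap = 1000L)        # gap 400: merged
  expect_equal(out[, c("start", "end")], data.frame(start = 0L, end = 6400L))
  expect_equal(out$n_source_hmrs, 2L)
  out2 <- cluster_hmrs(data.frame(chrom = "chr1", start = c(0L, 4500L),
                                  end = c(3000L, 6400L)), max_gap = 1000L)
  expect_equal(nrow(out2), 2)                        # gap 1500: unmerged
  # boundary: gap exactly max_gap merges
  out3 <- cluster_hmrs(data.frame(chrom = "chr1", start = c(0L, 4000L),
                                  end = c(3000L, 5000L)), max_gap = 1000L)
  expect_equal(nrow(out3), 1)
  # idempotent and order-invariant
  shuffled <- hmrs[c(2, 1), ]
  expect_equal(cluster_hmrs(shuffled, 1000L)[, 1:3], out[, 1:3])
  expect_equal(cluster_hmrs(out[, 1:3], 1000L)[, 1:3], out[, 1:3])
})

test_that("DMV calling applies the inclusive 5-kb cutoff", {
  merged <- data.frame(chrom = "chr1", start = c(0L, 10000L, 20000L),
                       end = c(6400L, 14999L, 25000L))
  dmv <- define_dmvs(merged)
  expect_equal(dmv$start, c(0L, 20000L))  # 6400 bp and exactly 5000 bp qualify
  expect_equal(nrow(define_dmvs(data.frame(chrom = "chr1", start = 0L,
                                           end = 4999L))), 0)
})

test_that("DMV sets are monotone in the clustering gap and length cutoff", {
  set.seed(31)
  hmrs <- data.frame(chrom = "chr1",
                     start = sort(sample.int(2e5, 40)))
  hmrs$end <- hmrs$start + sample(200:3000, 40, replace = TRUE)
  n_dmv <- function(gap, len) nrow(define_dmvs(cluster_hmrs(hmrs, gap), len))
  gaps <- c(100, 500, 1000, 2000, 5000)
  expect_true(all(diff(vapply(gaps, n_dmv, numeric(1), len = 5000)) >= 0))
  lens <- c(1000, 3000, 5000, 8000, 15000)
  expect_true(all(diff(vapply(lens, n_dmv, numeric(1), gap = 1000)) <= 0))
})

test_that("promoter methylation class prioritizes DMV over plain HMR overlap", {
  hmrs <- data.frame(chrom = "chr1",
                     start = c(0L, 1000L, 4000L, 50000L),
                     end = c(800L, 3500L, 9000L, 51000L))
  merged <- cluster_hmrs(hmrs, max_gap = 1000L)
  dmvs <- define_dmvs(merged)           # [0, 9000) only
  win <- data.frame(chrom = "chr1",
                    start = c(2000L, 50200L, 80000L),
                    end = c(4000L, 50400L, 82000L))
  expect_equal(promoter_methylation_class(win, dmvs, hmrs),
               c("DMV", "hypomethylated", "methylated"))
})

test_that("planted methylation and breadth structure is recovered from a cohort", {
  co <- test_cohort(seed = 11, n_genes = 400)
  genes <- co$genes
  win <- data.frame(gene = genes$gene, chrom = genes$chrom,
                    start = genes$tss - 1000L, end = genes$tss + 1000L)
  merged <- cluster_hmrs(co$hmr, 1000L)
  dmvs <- define_dmvs(merged)
  cls <- promoter_methylation_class(win, dmvs, co$hmr)
  arch <- co$truth$archetype
  # every always-poised promoter is hypomethylated; DMV fraction matches truth
  expect_true(all(cls[arch == "always_prcs5p"] %in% c("DMV", "hypomethylated")))
  expect_equal(cls[arch == "always_prcs5p"] == "DMV",
               co$truth$dmv_member[arch == "always_prcs5p"])
  frac_always <- mean(cls[arch == "always_prcs5p"] == "DMV")
  frac_inact <- mean(cls[arch == "prcs5p_to_inactive"] == "DMV")
  expect_gt(frac_always, frac_inact)
  # H3K27me3 domains at always-poised promoters are ~3x broader (day 30)
  breadth <- h3k27me3_breadth(win, co$regions$H3K27me3$day30)
  med_always <- median(breadth[arch == "always_prcs5p"])
  med_other <- median(breadth[arch == "prcs5p_to_prconly"])
  expect_equal(med_always / med_other, 3, tolerance = 0.15)
})
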