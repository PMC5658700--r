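test_that("hypergeometric tails match direct pmf summation", {
  universe <- paste0("g", 1:20)
  state <- universe[1:5]
  glist <- universe[c(1, 2, 3, 10, 11)]  # overlap 3
  res <- hypergeom_state_enrichment(glist, state, universe)
  ora <- oracle_hyper(20, 5, 5, 3)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_enrich, ora$enrich)
  expect_equal(res$p_deplete, ora$deplete)
  # boundary: zero overlap
  res0 <- hypergeom_state_enrichment(universe[6:10], universe[1:5], universe)
  expect_equal(res0$p_enrich, 1)
  expect_equal(res0$p_deplete, oracle_hyper(20, 5, 5, 0)$deplete)
  # degenerate: list = set = universe
  resall <- hypergeom_state_enrichment(universe, universe, universe)
  expect_equal(resall$p_enrich, 1)
  expect_equal(resall$p_deplete, 1)
  expect_error(hypergeom_state_enrichment(c(glist, "zz"), state, universe),
               "universe")
})

test_that("p_enrich + p_deplete = 1 + P(X = overlap)", {
  set.seed(12)
  for (i in 1:25) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    universe <- paste0("u", 1:N)
    res <- hypergeom_state_enrichment(sample(universe, n),
                                      sample(universe, K), universe)
    expect_equal(res$p_enrich + res$p_deplete,
                 1 + dhyper(res$overlap, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("influence ranks average per TF and stay within input range", {
  expect_equal(average_influence_rank(c(a = 10, b = 20, c = 60)), 30)
  expect_equal(average_influence_rank(c(only = 17)), 17)
  df <- data.frame(tf = c("Sox2", "Sox2", "Gata4"),
                   conversion = c("c1", "c2", "c1"),
                   rank = c(30, 39.72, 5))
  out <- average_influence_rank(df)
  expect_equal(out$mean_rank[out$tf == "Sox2"], 34.86)
  expect_equal(out$n_conversions[out$tf == "Sox2"], 2L)
  set.seed(4)
  r <- runif(10, 1, 303)
  expect_true(average_influence_rank(r) >= min(r) &&
                average_influence_rank(r) <= max(r))
  expect_error(average_influence_rank(numeric()), "no conversions")
})

test_that("rank-to-score puts high influence at the top of the ranking", {
  mr <- c(tf1 = 1, tf2 = 150, tf3 = 303)
  sc <- rank_to_score(mr, max_rank = 303)
  expect_equal(unname(sc), c(303, 154, 1))
  expect_equal(names(sort(sc, decreasing = TRUE))[1], "tf1")
})

test_that("homolog matching keeps 1:1 pairs and counts the rest", {
  tab <- data.frame(human_name = c("SOX2", "PAX6", "PAX6", "GATA4"),
                    mouse_name = c("Sox2", "Pax6", "Pax6b", "Gata4"))
  out <- match_homologs(c("SOX2", "PAX6", "NANOG", "GATA4"), tab)
  expect_equal(out$human_name, c("GATA4", "SOX2"))
  expect_equal(attr(out, "n_ambiguous"), 1)  # PAX6 maps to two mouse names
  expect_equal(attr(out, "n_unmatched"), 1)  # NANOG absent
})

test_that("enrichment score matches exhaustive running-sum evaluation", {
  scores <- c(f = 6, e = 5, d = 4, c = 3, b = 2, a = 1)
  res <- gsea_preranked(scores, c("f", "e"), n_permutations = 100, seed = 1)
  hit <- names(sort(scores, decreasing = TRUE)) %in% c("f", "e")
  expect_equal(res$es, oracle_es(sort(scores, decreasing = TRUE), hit))
  expect_gt(res$es, 0)
  expect_equal(res$direction, "top")
  # a set at the bottom scores negative
  res2 <- gsea_preranked(scores, c("a", "b"), n_permutations = 100, seed = 1)
  expect_lt(res2$es, 0)
  # random small sets: implementation equals the position-by-position oracle
  set.seed(88)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    sc <- setNames(sort(runif(n, 0.1, 10), decreasing = TRUE),
                   paste0("t", 1:n))
    set <- sample(names(sc), sample(1:(n - 1), 1))
    r <- gsea_preranked(sc, set, n_permutations = 100, seed = i)
    expect_es_equal(r$es, unname(sc), names(sc) %in% set)
  }
})

test_that("weight exponent 0 reduces to the unweighted statistic", {
  sc <- setNames(c(9, 7, 5, 3, 1), paste0("t", 1:5))
  r <- gsea_preranked(sc, c("t1", "t3"), weight_exponent = 0,
                      n_permutations = 100, seed = 2)
  expect_equal(r$es, oracle_es(unname(sc), c(TRUE, FALSE, TRUE, FALSE, FALSE),
                               p = 0))
})

test_that("the permutation null is reproducible bit-for-bit under a seed", {
  set.seed(990)
  sc <- setNames(runif(50), paste0("t", 1:50))
  a <- gsea_preranked(sc, names(sc)[1:8], n_permutations = 200, seed = 9)
  b <- gsea_preranked(sc, names(sc)[1:8], n_permutations = 200, seed = 9)
  expect_identical(a$null_es, b$null_es)
  expect_identical(a$nes, b$nes)
  c <- gsea_preranked(sc, names(sc)[1:8], n_permutations = 200, seed = 10)
  expect_false(identical(a$null_es, c$null_es))
  expect_error(gsea_preranked(sc, names(sc), n_permutations = 200),
               "as large as")
  expect_error(gsea_preranked(sc, c(names(sc)[1], "zz"), n_permutations = 200),
               "absent")
  expect_error(gsea_preranked(sc, names(sc)[1:2], n_permutations = 10), "100")
})

test_that("a uniformly spread set has an ES shrinking with list length", {
  mean_abs_es <- function(n) {
    sc <- setNames(seq(n, 1), paste0("t", 1:n))
    set <- paste0("t", seq(1, n, by = 10))  # every 10th gene
    abs(gsea_preranked(sc, set, n_permutations = 100, seed = 3)$es)
  }
  expect_gt(mean_abs_es(20), mean_abs_es(2000))
})

test_that("ES direction and size agree with fgsea on a fixture", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  sc <- setNames(rnorm(80), paste0("t", 1:80))
  set <- names(sort(sc, decreasing = TRUE))[c(1:6, 40)]
  ours <- gsea_preranked(sc, set, n_permutations = 500, seed = 5)
  ref <- suppressWarnings(
    fgsea::fgsea(list(s = set), sc, nPermSimple = 500, minSize = 1))
  expect_equal(ours$es, ref$ES, tolerance = 1e-6)
})

test_that("planted rank bias yields top-direction enrichment for the poised set", {
  co <- test_cohort(seed = 11, n_genes = 400)
  mr <- average_influence_rank(co$tf_ranks)
  scores <- rank_to_score(setNames(mr$mean_rank, mr$tf))
  sets <- split(co$tf_panel$tf, co$tf_panel$day30_state)
  res <- gsea_preranked_sets(scores, sets, n_permutations = 300, seed = 17)
  poised <- res[res$set == "PRC_S5p", ]
  expect_equal(poised$direction, "top")
  expect_lt(poised$fdr, 0.25)
})
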