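make_sets <- function(...) gene_set_collection(list(...))

test_that("hypergeometric ORA is exact on closed-form cases", {
  universe <- sprintf("G%02d", 1:20)
  sets <- make_sets(hit = universe[1:5], none = universe[6:10])
  # complete overlap of a size-5 set with a size-5 query: p = 1 / C(20,5)
  r <- ora_test(universe[1:5], sets, universe)
  expect_equal(r$p_value[r$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$overlap[r$set == "hit"], 5L)
  # zero overlap: P(X >= 0) = 1
  expect_equal(r$p_value[r$set == "none"], 1)
  expect_true(r$significant[r$set == "hit"])
  expect_false(r$significant[r$set == "none"])
})

test_that("ORA p equals exhaustive enumeration over all query draws (N <= 12)", {
  universe <- sprintf("U%02d", 1:10)
  set_members <- universe[c(1, 3, 5, 7)]
  sets <- make_sets(s = set_members)
  q_size <- 4
  draws <- combn(10, q_size)
  for (overlap_query in list(universe[c(1, 3, 2, 4)],   # overlap 2
                             universe[c(1, 3, 5, 2)],   # overlap 3
                             universe[c(2, 4, 6, 8)])) {# overlap 1
    k_obs <- length(intersect(overlap_query, set_members))
    p_got <- ora_test(overlap_query, sets, universe)$p_value
    # enumerate every possible query of this size; p = fraction with
    # overlap at least as large
    ge <- apply(draws, 2, function(ix)
      length(intersect(universe[ix], set_members)) >= k_obs)
    expect_equal(p_got, mean(ge), tolerance = 1e-12)
  }
})

test_that("ORA validates its inputs", {
  universe <- sprintf("U%d", 1:10)
  sets <- make_sets(s = universe[1:3])
  expect_error(ora_test(character(), sets, universe), "empty query")
  expect_error(ora_test("NOT_THERE", sets, universe), "not in the universe")
  expect_error(ora_test(universe[1], sets, character()), "universe")
})

test_that("enrichment score matches degenerate closed forms", {
  ranked <- setNames(c(5, 4, 3, 2, 1), sprintf("g%d", 1:5))
  # set = whole list
  expect_equal(gsea_enrichment_score(ranked, names(ranked))$es, 1)
  # single top-ranked gene, unweighted
  expect_equal(gsea_enrichment_score(ranked, "g1", weight_exponent = 0)$es, 1)
})

test_that("enrichment score equals an independent full running-sum walk", {
  set.seed(51)
  ranked <- setNames(sort(rnorm(5, 0, 2), decreasing = TRUE),
                     sprintf("g%d", 1:5))
  for (w in c(0, 1)) {
    for (members in list(c("g1", "g3"), c("g2", "g5"), c("g4", "g5"))) {
      got <- gsea_enrichment_score(ranked, members, w)
      expect_equal(got$es, walk_es_oracle(ranked, members, w),
                   tolerance = 1e-12)
    }
  }
  # larger random cases against the same oracle
  for (r in 1:20) {
    N <- sample(8:30, 1)
    ranked <- setNames(sort(rnorm(N), decreasing = TRUE),
                       sprintf("x%03d", seq_len(N)))
    members <- sample(names(ranked), sample(2:5, 1))
    got <- gsea_enrichment_score(ranked, members, 1)$es
    expect_equal(got, walk_es_oracle(ranked, members, 1), tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with the fgsea reference statistic", {
  set.seed(52)
  ranked <- setNames(sort(rnorm(50), decreasing = TRUE),
                     sprintf("g%02d", 1:50))
  members <- sample(names(ranked), 8)
  ours <- gsea_enrichment_score(ranked, members, weight_exponent = 1)$es
  ref <- fgsea::calcGseaStat(ranked, selectedStats = which(names(ranked) %in% members),
                             gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("ES stays in [-1, 1] and reversal negates it when unweighted", {
  set.seed(53)
  for (r in 1:50) {
    N <- sample(6:40, 1)
    ranked <- setNames(sort(rnorm(N), decreasing = TRUE),
                       sprintf("y%03d", seq_len(N)))
    members <- sample(names(ranked), sample(1:(N - 1), 1))
    es <- gsea_enrichment_score(ranked, members, 1)$es
    expect_true(es >= -1 && es <= 1)
    sc <- gsea_enrichment_score(ranked, members, 0)
    rev_ranked <- setNames(rev(-unname(ranked)), rev(names(ranked)))
    es0_rev <- gsea_enrichment_score(rev_ranked, members, 0)$es
    # when the peak and trough have exactly equal magnitude the signed
    # extremum is ambiguous; negation is only defined off that tie
    if (abs(max(sc$running) + min(sc$running)) > 1e-9)
      expect_equal(es0_rev, -sc$es, tolerance = 1e-12)
    else
      expect_equal(abs(es0_rev), abs(sc$es), tolerance = 1e-12)
  }
})

test_that("exhaustive permutation p matches hand enumeration at N = 6, set of 2", {
  ranked <- setNames(c(3, 2, 1, -1, -2, -3), sprintf("g%d", 1:6))
  sets <- make_sets(top = c("g1", "g2"))
  r <- gsea_preranked(ranked, sets, min_size = 1, exhaustive = TRUE)
  # enumerate all C(6,2) = 15 label placements
  es_obs <- gsea_enrichment_score(ranked, c("g1", "g2"))$es
  all_es <- apply(combn(6, 2), 2, function(ix)
    gsea_enrichment_score(ranked, names(ranked)[ix])$es)
  same_sign <- if (es_obs >= 0) all_es[all_es >= 0] else all_es[all_es < 0]
  p_manual <- (1 + sum(abs(same_sign) >= abs(es_obs))) / (1 + length(same_sign))
  expect_equal(r$p_value[r$set == "top"], p_manual, tolerance = 1e-12)
  expect_equal(attr(r, "n_perm"), 15L)
})

test_that("seeded GSEA runs are bit-reproducible", {
  set.seed(61)
  ranked <- setNames(sort(rnorm(100), decreasing = TRUE),
                     sprintf("g%03d", 1:100))
  sets <- make_sets(a = sprintf("g%03d", 1:10), b = sprintf("g%03d", 40:55))
  r1 <- gsea_preranked(ranked, sets, n_perm = 200, seed = 99)
  r2 <- gsea_preranked(ranked, sets, n_perm = 200, seed = 99)
  expect_identical(r1, r2)
})

test_that("a planted top-of-ranking set is called significant and decoys are not", {
  set.seed(62)
  N <- 200
  ranked <- setNames(sort(rnorm(N, 0, 1), decreasing = TRUE),
                     sprintf("g%03d", seq_len(N)))
  ranked[1:15] <- ranked[1:15] + 3  # strong signal at the top
  ranked <- sort(ranked, decreasing = TRUE)
  sets <- make_sets(planted = names(ranked)[1:15],
                    decoy = sample(names(ranked), 15))
  r <- gsea_preranked(ranked, sets, n_perm = 1000, seed = 7)
  expect_true(r$significant[r$set == "planted"])
  expect_true(r$es[r$set == "planted"] > 0)
  expect_gt(r$nes[r$set == "planted"], 1)
})

test_that("permutation p-values are valid under the null", {
  set.seed(63)
  N <- 100
  n_rep <- 60
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    ranked <- setNames(sort(rnorm(N), decreasing = TRUE),
                       sprintf("g%03d", seq_len(N)))
    sets <- make_sets(s = sample(names(ranked), 10))
    pvals[i] <- gsea_preranked(ranked, sets, n_perm = 200, seed = i,
                               min_size = 1)$p_value
  }
  for (alpha in c(0.05, 0.1, 0.25)) {
    # binomial slack: 3 SDs above alpha
    slack <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(pvals <= alpha), alpha + slack)
  }
})

test_that("sets outside the ranking or the size bounds are skipped with a record", {
  ranked <- setNames(c(3, 2, 1, -1), sprintf("g%d", 1:4))
  sets <- make_sets(ok = c("g1", "g2"), gone = c("zz1", "zz2"),
                    tiny = "g3")
  r <- gsea_preranked(ranked, sets, n_perm = 50, seed = 1, min_size = 2)
  expect_setequal(attr(r, "skipped"), c("gone", "tiny"))
  expect_equal(r$set, "ok")
})
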