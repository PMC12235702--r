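test_that("log2 transform and median centering behave as defined", {
  m <- matrix(2^c(10, 10, 10, 12, 14, 16), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  d <- data.frame(sample = c("a", "b"), condition = c("CTL", "PS"),
                  batch = 1L)
  q <- protein_quant(c("p1", "p2", "p3"), c("g1", "g2", "g3"), m, design = d)

  n0 <- normalize_quant(q, method = "none")
  expect_equal(n0$intensities[, "a"], rep(10, 3), ignore_attr = TRUE)

  nc <- normalize_quant(q)
  # constant column becomes all zero; per-sample median is 0 afterwards
  expect_equal(nc$intensities[, "a"], rep(0, 3), ignore_attr = TRUE)
  expect_equal(apply(nc$intensities, 2, median), c(a = 0, b = 0),
               tolerance = 1e-12)

  m[, 1] <- NA
  q2 <- protein_quant(c("p1", "p2", "p3"), c("g1", "g2", "g3"), m, design = d)
  expect_error(normalize_quant(q2), "all values missing: a")
})

test_that("identical groups give zero fold change, t = 0, p = 1", {
  mat <- matrix(rep(c(10, 11, 12), 2), 3, 6, byrow = FALSE)
  mat <- rbind(mat, mat)  # a couple of proteins
  r <- dep_compare(toy_quant_3v3(mat), "PS", "CTL")
  expect_equal(r$log2_fc, rep(0, nrow(r)))
  expect_equal(r$t_stat, rep(0, nrow(r)))
  expect_equal(r$p_value, rep(1, nrow(r)))
  expect_false(any(r$is_dep))
})

test_that("doubled abundance with zero within-group variance is flagged with log2_fc = 1", {
  mat <- matrix(c(10, 10, 10, 11, 11, 11), 1, 6)
  r <- dep_compare(toy_quant_3v3(mat), "PS", "CTL")
  expect_equal(r$log2_fc, 1)
  expect_true(r$flagged)
  expect_true(is.na(r$p_value))
  expect_false(r$is_dep)
})

test_that("t and p match the closed-form pooled-variance computation and t.test", {
  set.seed(31)
  mat <- matrix(rnorm(20 * 6, 10, 1), 20, 6)
  r <- dep_compare(toy_quant_3v3(mat), "PS", "CTL")
  for (i in seq_len(nrow(mat))) {
    den <- mat[i, 1:3]; num <- mat[i, 4:6]
    # textbook pooled-SD Student t with df = 4
    sp <- sqrt((2 * var(num) + 2 * var(den)) / 4)
    t_manual <- (mean(num) - mean(den)) / (sp * sqrt(1 / 3 + 1 / 3))
    p_manual <- 2 * pt(-abs(t_manual), df = 4)
    expect_equal(r$t_stat[i], t_manual, tolerance = 1e-10)
    expect_equal(r$p_value[i], p_manual, tolerance = 1e-10)
    tt <- t.test(num, den, var.equal = TRUE)
    expect_equal(r$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("Welch option matches t.test(var.equal = FALSE)", {
  set.seed(32)
  mat <- matrix(rnorm(10 * 6, 10, 1), 10, 6)
  mat[, 4:6] <- mat[, 4:6] * 1.5
  r <- dep_compare(toy_quant_3v3(mat), "PS", "CTL", var_equal = FALSE)
  tt <- t.test(mat[3, 4:6], mat[3, 1:3])
  expect_equal(r$p_value[3], tt$p.value, tolerance = 1e-10)
})

test_that("swapping numerator and denominator negates log2FC and preserves p", {
  set.seed(33)
  mat <- matrix(rnorm(50 * 6, 10, 1), 50, 6)
  q <- toy_quant_3v3(mat)
  a <- dep_compare(q, "PS", "CTL")
  b <- dep_compare(q, "CTL", "PS")
  expect_identical(a$log2_fc, -b$log2_fc)
  expect_identical(a$p_value, b$p_value)
})

test_that("proteins with insufficient replicates are flagged, not dropped", {
  mat <- matrix(rnorm(3 * 6, 10, 1), 3, 6)
  mat[2, c(1, 2)] <- NA  # only one CTL value left
  r <- dep_compare(toy_quant_3v3(mat), "PS", "CTL")
  expect_equal(nrow(r), 3L)
  expect_true(r$flagged[2])
  expect_true(is.na(r$p_value[2]))
  expect_false(r$flagged[1])
})

test_that("batch scoping restricts the groups and errors when empty", {
  mat <- matrix(rnorm(2 * 12, 10, 1), 2, 12)
  colnames(mat) <- sprintf("x%d", 1:12)
  design <- data.frame(sample = colnames(mat),
                       condition = rep(c("CTL", "PS"), 6),
                       batch = rep(1:2, each = 6))
  q <- protein_quant(c("p1", "p2"), c("g1", "g2"), mat, design = design,
                     log2 = TRUE)
  r1 <- dep_compare(q, "PS", "CTL", batch = 1)
  expect_equal(unique(r1$n_num), 3L)
  expect_error(dep_compare(q, "PS", "P", batch = 1), "P/PS|empty")
})

test_that("the DEP rule equals a brute-force row scan", {
  set.seed(34)
  n <- 1000
  mat <- matrix(rnorm(n * 6, 10, 0.3), n, 6)
  idx <- sample(n, 100)
  mat[idx, 4:6] <- mat[idx, 4:6] + sample(c(-1, 1), 100, TRUE) * runif(100, 0.3, 1.5)
  r <- dep_compare(toy_quant_3v3(mat), "PS", "CTL")
  brute <- logical(n)
  for (i in seq_len(n)) {
    tt <- t.test(mat[i, 4:6], mat[i, 1:3], var.equal = TRUE)
    lfc <- mean(mat[i, 4:6]) - mean(mat[i, 1:3])
    brute[i] <- tt$p.value < 0.05 && abs(lfc) > 0.58
  }
  expect_identical(r$is_dep, brute)
  deps <- filter_deps(r, use_genes = FALSE)
  expect_setequal(c(deps$up, deps$down), r$protein_id[brute])
  expect_true(all(r$log2_fc[r$protein_id %in% deps$up] > 0))
})

test_that("the DEP rule thresholds behave at the boundaries", {
  # p just under 0.05 with |lfc| over/under 0.58
  r <- structure(data.frame(protein_id = c("a", "b"), gene = c("A", "B"),
                            log2_fc = c(0.60, 0.50), p_value = c(0.04, 0.04),
                            is_dep = c(TRUE, FALSE)),
                 class = c("dep_result", "data.frame"),
                 p_threshold = 0.05, fc_threshold = 0.58)
  d <- filter_deps(r)
  expect_equal(d$up, "A")
  expect_equal(length(d$down), 0L)
})

test_that("the SD-rule down list equals a brute-force z computation", {
  set.seed(35)
  n <- 400
  mat <- matrix(rnorm(n * 6, 10, 0.3), n, 6)
  mat[1:40, 4:6] <- mat[1:40, 4:6] - runif(40, 0.5, 2)
  r <- dep_compare(toy_quant_3v3(mat), "PS", "CTL")
  got <- filter_sd_down(r, use_genes = FALSE)
  z <- (r$log2_fc - mean(r$log2_fc)) / sd(r$log2_fc)
  want <- r$protein_id[r$p_value < 0.05 & z < -1.96]
  expect_setequal(got, want)
  # z = -2 in, z = -1 out (given p passes)
  expect_true(all(z[r$protein_id %in% got] < -1.96))
})

test_that("volcano table applies the exact -log10 transform and flags floors", {
  r <- structure(data.frame(protein_id = c("a", "b", "c"),
                            gene = c("A", "B", "C"),
                            log2_fc = c(1, 0, -1),
                            p_value = c(0.01, 1, 0),
                            is_dep = c(TRUE, FALSE, FALSE)),
                 class = c("dep_result", "data.frame"),
                 p_threshold = 0.05, fc_threshold = 0.58)
  v <- volcano_table(r)
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$neg_log10_p[2], 0)
  expect_true(v$p_floored[3] && is.finite(v$neg_log10_p[3]))
  expect_identical(v$is_dep, r$is_dep)
})

test_that("identical input gives bit-identical result tables", {
  set.seed(36)
  mat <- matrix(rnorm(100 * 6, 10, 1), 100, 6)
  q <- toy_quant_3v3(mat)
  expect_identical(dep_compare(q, "PS", "CTL"), dep_compare(q, "PS", "CTL"))
})

test_that("rankings from a comparison are sorted and deduplicated", {
  r <- structure(data.frame(protein_id = c("a", "b", "c", "d"),
                            gene = c("G1", "G2", "G2", ""),
                            log2_fc = c(1, -2, 3, 5),
                            p_value = c(0.5, 0.01, 0.2, 0.1)),
                 class = c("dep_result", "data.frame"))
  rk <- dep_ranking(r)
  expect_equal(names(rk), c("G1", "G2"))  # G2 keeps its smaller-p row
  expect_equal(unname(rk), c(1, -2))
})
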