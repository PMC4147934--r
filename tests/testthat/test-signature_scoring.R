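test_that("running-sum walk matches hand-enumerated configurations", {
  # N = 4, S = 2, zero-sum weights are d_in = 1, d_out = -1
  top <- gsea_walk(c(TRUE, TRUE, FALSE, FALSE))       # sums 1,2,1,0
  expect_equal(top, list(positive = 2, negative = 0, total = 2))
  bottom <- gsea_walk(c(FALSE, FALSE, TRUE, TRUE))    # sums -1,-2,-1,0
  expect_equal(bottom, list(positive = 0, negative = -2, total = 2))
  spread <- gsea_walk(c(TRUE, FALSE, TRUE, FALSE))    # sums 1,0,1,0
  expect_equal(spread, list(positive = 1, negative = 0, total = 1))
})

test_that("walk agrees with the brute-force oracle on random configurations", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    s <- sample(seq_len(n - 1), 1)
    in_set <- sample(c(rep(TRUE, s), rep(FALSE, n - s)))
    for (variant in c("zero_sum_ks", "literal")) {
      w <- walk_weights(n, s, variant)
      expect_equal(gsea_walk(in_set, variant),
                   walk_oracle(in_set, w$d_in, w$d_out))
    }
  }
})

test_that("walk rejects degenerate sets and exposes both weight variants", {
  expect_error(gsea_walk(rep(TRUE, 4)), "S < N")
  expect_error(gsea_walk(rep(FALSE, 4)), "1 <= S")
  w <- walk_weights(10, 3, "literal")
  expect_equal(w$d_in, 7 / 3)
  expect_equal(w$d_out, -3 / 7)
  # literal walk terminates at N - 2S, not 0
  expect_equal(sum(ifelse(c(rep(TRUE, 3), rep(FALSE, 7)), w$d_in, w$d_out)),
               10 - 2 * 3, tolerance = 1e-12)
})

test_that("signed walk reports the dominant excursion with its sign", {
  expect_equal(gsea_walk(c(TRUE, TRUE, FALSE, FALSE), signed = TRUE)$total, 2)
  expect_equal(gsea_walk(c(FALSE, FALSE, TRUE, TRUE), signed = TRUE)$total, -2)
})

test_that("complement symmetry holds for equal-magnitude weights at S = N/2", {
  set.seed(7)
  for (i in 1:20) {
    n <- 2 * sample(3:12, 1)
    in_set <- sample(c(rep(TRUE, n / 2), rep(FALSE, n / 2)))
    expect_equal(gsea_walk(in_set)$total, gsea_walk(!in_set)$total)
  }
})

test_that("raw scores are invariant to per-gene constants and permutations", {
  sim <- small_sim()
  expr <- sim$expr[, 1:8]
  sets <- sim$sets[1:4]
  base <- compute_raw_scores(expr, sets)

  shifted <- expr
  shifted["g0005", ] <- shifted["g0005", ] + 100  # constant within the gene
  expect_equal(compute_raw_scores(shifted, sets), base)

  perm <- sample(ncol(expr))
  permuted <- compute_raw_scores(expr[, perm], sets)
  expect_equal(permuted, base[, perm])
})

test_that("a top-ranked set scores exactly as the top-block walk", {
  set.seed(3)
  n <- 50
  expr <- matrix(rnorm(n * 3), n,
                 dimnames = list(sprintf("g%02d", 1:n), c("a", "b", "c")))
  # make sample "a" rank the first 5 genes strictly on top after centering
  expr[1:5, "a"] <- expr[1:5, "a"] + 100
  sets <- list(top5 = rownames(expr)[1:5])
  raw <- compute_raw_scores(expr, sets)
  block <- gsea_walk(c(rep(TRUE, 5), rep(FALSE, n - 5)))
  expect_equal(raw["top5", "a"], block$total)
})

test_that("related-set reduction averages groups and passes the rest through", {
  raw <- matrix(c(0.2, 0.4, 0.5, 0.9), 4, 1,
                dimnames = list(c("A", "B", "C", "D"), "s1"))
  red <- reduce_related_sets(raw, list(M1 = c("A", "B"), M2 = "C"))
  expect_equal(red["M1", "s1"], 0.3)
  expect_equal(red["M2", "s1"], 0.5)
  expect_equal(red["D", "s1"], 0.9)
  expect_identical(rownames(red), c("M1", "M2", "D"))

  expect_equal(reduce_related_sets(raw, NULL), raw)
  ident <- reduce_related_sets(raw, list(A = "A", B = "B", C = "C", D = "D"))
  expect_equal(unname(ident), unname(raw))
  expect_error(reduce_related_sets(raw, list(M = c("A", "X"))), "X")
  expect_error(reduce_related_sets(raw, list(M = "A", N = c("A", "B"))),
               "more than one group")
})

test_that("per-sample and per-set normalization rescale onto [0, 1]", {
  raw <- matrix(c(2, 4, 6, 3, 3, 3), nrow = 3,
                dimnames = list(c("x", "y", "z"), c("s1", "s2")))
  expect_warning(sig <- normalize_signatures(raw, "per_sample"), "constant")
  expect_equal(unname(sig[, "s1"]), c(0, 0.5, 1))
  expect_equal(unname(sig[, "s2"]), c(0.5, 0.5, 0.5))
  expect_identical(attr(sig, "normalization_mode"), "per_sample")

  per_set <- normalize_signatures(raw[1:2, , drop = FALSE], "per_set")
  for (i in 1:2) expect_equal(range(per_set[i, ]), c(0, 1))
})

test_that("random-set p-values use add-one smoothing", {
  set.seed(9)
  n <- 200
  expr <- matrix(rnorm(n * 3), n,
                 dimnames = list(sprintf("g%03d", 1:n), c("a", "b", "c")))
  expr[1:10, "a"] <- expr[1:10, "a"] + 50  # unbeatable top block in sample a
  sets <- list(hot = rownames(expr)[1:10])
  raw <- compute_raw_scores(expr, sets)
  p <- normalize_signatures(raw, "random_set_pvalue", expr = expr,
                            sets = sets, B = 99, seed = 1)
  expect_equal(p["hot", "a"], 1 / 100)
  expect_true(all(p > 0 & p <= 1))
})

test_that("scores depend only on the ranking of centered values", {
  sim <- small_sim()
  expr <- sim$expr[, 1:6]
  sets <- sim$sets[1:3]
  base <- compute_raw_scores(expr, sets)
  # apply a strictly increasing transform to each sample's centered values,
  # then undo the centering shift so compute_raw_scores re-centers to the
  # same ranking
  centered <- expr - rowMeans(expr)
  ranked <- apply(centered, 2, rank, ties.method = "first")
  dimnames(ranked) <- dimnames(expr)
  ranked_scores <- vapply(colnames(expr), function(s) {
    ord <- order(centered[, s], decreasing = TRUE, method = "radix")
    vapply(sets, function(g) {
      gsea_walk(rownames(expr)[ord] %in% g)$total
    }, numeric(1))
  }, numeric(length(sets)))
  expect_equal(unname(base), unname(ranked_scores))
})
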