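test_that("pairwise correlations behave on degenerate pairs", {
  sig <- cbind(a = c(0.1, 0.5, 0.9), b = c(0.1, 0.5, 0.9),
               c = c(0.9, 0.5, 0.1))
  rownames(sig) <- paste0("set", 1:3)
  corr <- pairwise_signature_correlations(sig)
  expect_equal(corr["a", "b"], 1)
  expect_equal(corr["a", "c"], -1)
  expect_equal(corr, t(corr))
  expect_equal(unname(diag(corr)), rep(1, 3))

  sig_flat <- cbind(sig, flat = c(0.2, 0.2, 0.2))
  expect_error(pairwise_signature_correlations(sig_flat), "flat")
})

wb_md <- function(ids, patients, types, gleason) {
  data.frame(sample_id = ids, patient_id = patients, sample_type = types,
             gleason = gleason, frac_normal = ifelse(types == "normal", 1, 0.2))
}

test_that("within/between pair enumeration matches hand counts", {
  sig <- matrix(runif(4 * 3), 4, 3,
                dimnames = list(paste0("set", 1:4), c("c1", "c2", "c3")))
  corr <- pairwise_signature_correlations(sig)

  md <- wb_md(c("c1", "c2", "c3"), c("P1", "P1", "P2"),
              rep("cancer", 3), c(7, 8, 7))
  rep_pat <- within_between_split(corr, md, "patient")
  expect_length(rep_pat$within_values, 1)
  expect_length(rep_pat$between_values, 2)
  expect_equal(rep_pat$within_values, corr["c1", "c2"])

  md_gl <- wb_md(c("c1", "c2", "c3"), c("P1", "P2", "P3"),
                 rep("cancer", 3), c(6, 6, 8))
  rep_gl <- within_between_split(corr, md_gl, "gleason")
  expect_equal(rep_gl$within_values, corr["c1", "c2"])
  expect_length(rep_gl$between_values, 2)
})

test_that("normal-vs-cancer split keys on shared patients", {
  sig <- matrix(runif(4 * 3), 4, 3,
                dimnames = list(paste0("set", 1:4), c("n1", "c1", "c2")))
  corr <- pairwise_signature_correlations(sig)
  md <- wb_md(c("n1", "c1", "c2"), c("P1", "P1", "P2"),
              c("normal", "cancer", "cancer"), c(NA, 7, 8))
  rep_nc <- within_between_split(corr, md, "normal_vs_cancer_patient")
  expect_equal(rep_nc$within_values, corr["n1", "c1"])
  expect_equal(rep_nc$between_values, corr["n1", "c2"])

  rep_st <- within_between_split(corr, md, "sample_type")
  expect_equal(rep_st$within_values, corr["c1", "c2"])  # only cancer-cancer
  expect_length(rep_st$between_values, 2)
})

test_that("every eligible pair lands on exactly one side", {
  sim <- small_sim(seed = 9)
  sig <- normalize_signatures(compute_raw_scores(sim$expr, sim$sets),
                              "per_sample")
  md <- sim$metadata
  corr <- pairwise_signature_correlations(sig)
  n_cancer <- sum(md$sample_type == "cancer")
  n_normal <- sum(md$sample_type == "normal")
  rep_pat <- within_between_split(corr, md, "patient")
  expect_equal(length(rep_pat$within_values) + length(rep_pat$between_values),
               choose(n_cancer, 2))
  rep_st <- within_between_split(corr, md, "sample_type")
  expect_equal(length(rep_st$within_values) + length(rep_st$between_values),
               choose(ncol(sig), 2))
  rep_nc <- within_between_split(corr, md, "normal_vs_cancer_patient")
  expect_equal(length(rep_nc$within_values) + length(rep_nc$between_values),
               n_cancer * n_normal)
})

test_that("a grouping with an empty side errors", {
  sig <- matrix(runif(4 * 3), 4, 3,
                dimnames = list(paste0("set", 1:4), c("c1", "c2", "c3")))
  corr <- pairwise_signature_correlations(sig)
  md <- wb_md(c("c1", "c2", "c3"), c("P1", "P2", "P3"),
              rep("cancer", 3), c(7, 8, 9))  # no within-patient pairs
  expect_error(within_between_split(corr, md, "patient"), "within")
})

test_that("group comparison agrees with an exact rank-sum oracle", {
  x <- c(0.1, 0.25, 0.4)
  y <- c(0.6, 0.75, 0.9, 0.8)
  expect_equal(compare_groups(x, y), ranksum_exact_p(x, y), tolerance = 1e-10)

  expect_equal(suppressWarnings(compare_groups(c(0.1, 0.2), c(0.1, 0.2))), 1)

  set.seed(13)
  wide_x <- rnorm(50, 0); wide_y <- rnorm(50, 3)
  expect_lt(compare_groups(wide_x, wide_y), 0.001)

  expect_error(compare_groups(numeric(0), y), "non-empty")
})

test_that("clustering merges identical samples first and is deterministic", {
  set.seed(17)
  sig <- matrix(runif(6 * 5), 6, 5,
                dimnames = list(paste0("set", 1:6), paste0("s", 1:5)))
  sig[, "s4"] <- sig[, "s1"]  # exact duplicate
  cl <- cluster_signatures(sig)
  first_merge <- cl$hclust$merge[1, ]
  expect_setequal(colnames(sig)[-first_merge], c("s1", "s4"))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_true(!is.unsorted(cl$hclust$height))

  cl2 <- cluster_signatures(sig)
  expect_identical(cl$leaf_order, cl2$leaf_order)
})

test_that("well-separated groups are contiguous in leaf order", {
  base1 <- c(1, 1, 1, 0, 0, 0); base2 <- c(0, 0, 0, 1, 1, 1)
  set.seed(19)
  sig <- sapply(1:6, function(i) {
    b <- if (i <= 3) base1 else base2
    b + rnorm(6, 0, 0.05)
  })
  dimnames(sig) <- list(paste0("set", 1:6), paste0("s", 1:6))
  ord <- cluster_signatures(sig)$leaf_order
  groups <- as.integer(sub("s", "", ord)) <= 3
  expect_equal(length(rle(groups)$lengths), 2)  # two contiguous blocks
})

test_that("ordered matrix export permutes rows and columns only", {
  sim <- small_sim(seed = 23)
  sig <- normalize_signatures(compute_raw_scores(sim$expr[, 1:10],
                                                 sim$sets), "per_sample")
  ord <- order_signature_matrix(sig)
  expect_setequal(rownames(ord), rownames(sig))
  expect_setequal(colnames(ord), colnames(sig))
  expect_equal(sort(as.vector(ord)), sort(as.vector(sig)))
})

test_that("neighbor counts match hand enumeration", {
  expect_equal(neighbor_same_patient_stat(c("A", "A", "B", "B"),
                                          n_perm = 10, seed = 1)$observed, 4)
  expect_equal(neighbor_same_patient_stat(c("A", "B", "A", "B"),
                                          n_perm = 10, seed = 1)$observed, 0)
  expect_equal(neighbor_same_patient_stat(c("A", "B", "B", "C", "A"),
                                          n_perm = 10, seed = 1)$observed, 2)
  expect_error(neighbor_same_patient_stat("A"), "2 leaves")
})

test_that("permutation expectation converges to the exhaustive value", {
  for (labels in list(c("A", "A", "B", "B"),
                      c("A", "A", "A", "B"),
                      c("A", "B", "C", "A", "B", "C"))) {
    exact <- adjacency_expectation_exact(labels)
    res <- neighbor_same_patient_stat(labels, n_perm = 5000, seed = 3)
    expect_equal(res$expected, exact, tolerance = 0.1)
  }
  expect_equal(adjacency_expectation_exact(c("A", "A", "B", "B")), 2)
})
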