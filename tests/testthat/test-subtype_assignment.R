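test_that("equal correlations give Z = 0 and p = 0.5 exactly", {
  for (rkh in c(-0.5, 0, 0.7)) {
    res <- steiger_test(0.5, 0.5, rkh, 15)
    expect_identical(res$Z, 0)
    expect_identical(res$p, 0.5)
  }
})

test_that("the Z statistic is antisymmetric in the two correlations", {
  set.seed(11)
  for (i in 1:50) {
    x <- rmvnorm3(15, 0.4, 0.1, 0.3)
    r <- cor(x)
    a <- steiger_test(r[1, 2], r[1, 3], r[2, 3], 15)
    b <- steiger_test(r[1, 3], r[1, 2], r[2, 3], 15)
    expect_equal(a$Z, -b$Z)
    expect_equal(a$p, 1 - b$p)
  }
})

test_that("the test matches an independent rendering of the published formula", {
  cases <- list(c(0.9, 0.1, 0, 15), c(0.6, -0.2, 0.3, 15),
                c(0.3, 0.25, 0.8, 40), c(-0.5, 0.5, -0.4, 10))
  for (cs in cases) {
    expect_equal(steiger_test(cs[1], cs[2], cs[3], cs[4])$p,
                 steiger_oracle_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  # frozen spot value for the documentation example
  res <- steiger_test(0.9, 0.1, 0, 15)
  expect_equal(res$Z, 3.18797066, tolerance = 1e-7)
  expect_equal(res$p, 0.000716375, tolerance = 1e-6)
})

test_that("preconditions are enforced", {
  expect_error(steiger_test(0.5, 0.2, 0, 3), "n >= 4")
  expect_error(steiger_test(1, 0.2, 0, 15), "strictly")
  expect_error(steiger_test(0.5, -1, 0, 15), "strictly")
})

test_that("two-sided option doubles the smaller tail", {
  one <- steiger_test(0.8, 0.2, 0.1, 15, sided = "one")
  two <- steiger_test(0.8, 0.2, 0.1, 15, sided = "two")
  expect_equal(two$p, 2 * min(one$p, 1 - one$p))
})

test_that("exclusive assignment requires dominance over every subtype", {
  r_ref <- diag(4); dimnames(r_ref) <- list(LETTERS[1:4], LETTERS[1:4])
  equal <- setNames(rep(0.4, 4), LETTERS[1:4])
  expect_identical(assign_exclusive(equal, 0.5, r_ref = r_ref, n = 15)$call,
                   "unassigned")

  strong <- setNames(c(0.95, 0.02, -0.05, 0.01), LETTERS[1:4])
  res <- assign_exclusive(strong, 0.05, r_ref = r_ref, n = 15)
  expect_identical(res$call, "A")
  expect_true(all(res$pvalues["A", -1] < 0.05))
})

test_that("prognosis assignment needs dominance over the other category only", {
  r_ref <- diag(4)
  dimnames(r_ref) <- list(PROSIG_SUBTYPES, PROSIG_SUBTYPES)
  r <- setNames(c(0.8, 0.1, -0.2, -0.3), PROSIG_SUBTYPES)
  prog <- assign_prognosis(r, 0.05, bad = PROSIG_SUBTYPES[1:2],
                           good = PROSIG_SUBTYPES[3:4], r_ref = r_ref, n = 15)
  expect_identical(prog$call, "bad")
  # exclusive mode may fail because BP-E/P/Pr vs BP-ERG need not differ:
  # here it succeeds or not, but the prognosis call must not depend on it
  equal <- setNames(rep(0.2, 4), PROSIG_SUBTYPES)
  expect_identical(assign_prognosis(equal, 0.25, r_ref = r_ref, n = 15)$call,
                   "unassigned")
})

test_that("bad and good prognosis calls are mutually exclusive on real correlations", {
  refs <- make_reference_from_truth(small_sim())
  r_ref <- inter_reference_correlations(refs)
  set.seed(21)
  for (i in 1:400) {
    sig <- runif(ncol(refs))
    r <- as.vector(cor(sig, t(refs)))
    names(r) <- rownames(refs)
    for (alpha in c(0.05, 0.25, 0.5)) {
      res <- assign_prognosis(r, alpha, bad = rownames(refs)[1:2],
                              good = rownames(refs)[3:4],
                              r_ref = r_ref, n = ncol(refs))
      expect_true(res$call %in% c("bad", "good", "unassigned"))
    }
  }
})

test_that("assignments are monotone in the threshold", {
  sim <- small_sim(seed = 5)
  refs <- make_reference_from_truth(sim)
  sig <- normalize_signatures(
    compute_raw_scores(sim$expr, sim$sets, signed = TRUE), "per_sample")
  corrs <- correlate_cohort(sig, refs)
  for (mode in c("prognosis", "exclusive")) {
    calls <- assign_cohort(corrs, mode = mode,
                           alpha = c(0.05, 0.25, 0.5))
    wide <- reshape(calls, idvar = "sample_id", timevar = "alpha",
                    direction = "wide")
    for (i in seq_len(nrow(wide))) {
      c05 <- wide[i, "call.0.05"]; c25 <- wide[i, "call.0.25"]
      c50 <- wide[i, "call.0.5"]
      if (c05 != "unassigned") expect_identical(c25, c05)
      if (c25 != "unassigned") expect_identical(c50, c25)
    }
  }
})

test_that("alpha outside (0, 0.5] is refused", {
  r_ref <- diag(4); dimnames(r_ref) <- list(LETTERS[1:4], LETTERS[1:4])
  r <- setNames(c(0.5, 0.1, 0, -0.1), LETTERS[1:4])
  expect_error(assign_exclusive(r, 0.6, r_ref = r_ref, n = 15), "alpha")
  expect_error(assign_prognosis(r, 0, r_ref = r_ref, n = 15), "alpha")
})

test_that("assignment summaries count calls by stratum with zero-padding", {
  calls <- data.frame(
    sample_id = rep(c("s1", "s2", "s3"), times = 2),
    alpha = rep(c(0.05, 0.25), each = 3),
    call = c("bad", "unassigned", "good", "bad", "bad", "good"))
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   patient_id = c("P1", "P2", "P3"),
                   sample_type = c("cancer", "cancer", "normal"),
                   gleason = c(7, 9, NA), frac_normal = c(0.1, 0.5, 1))
  tab <- summarize_assignments(calls, md)
  pick <- function(st, s, a, cl)
    tab$count[tab$stratifier == st & tab$stratum == s &
              tab$alpha == a & tab$call == cl]
  expect_equal(pick("overall", "all", 0.05, "bad"), 1)
  expect_equal(pick("overall", "all", 0.25, "bad"), 2)
  expect_equal(pick("sample_type", "normal", 0.05, "good"), 1)
  expect_equal(pick("gleason_group", "8-9", 0.25, "bad"), 1)
  expect_equal(pick("frac_normal_bin", "(0.4,0.6]", 0.05, "unassigned"), 1)
  # counts at the stricter threshold never exceed the looser one
  for (cl in c("bad", "good")) {
    expect_lte(pick("overall", "all", 0.05, cl),
               pick("overall", "all", 0.25, cl))
  }
  empty <- summarize_assignments(calls[0, ], md)
  expect_true(nrow(empty) == 0 || sum(empty$count) == 0)
})
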