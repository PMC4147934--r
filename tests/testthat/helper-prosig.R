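# Shared fixtures and independent oracles.

# Tiny deterministic expression matrix (4 genes x 3 samples).
tiny_expr <- function() {
  m <- matrix(c(5.0, 1.0, 2.0,
                1.0, 4.0, 1.5,
                0.5, 0.5, 3.0,
                2.0, 2.0, 2.0),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC", "gD"),
                              c("s1", "s2", "s3")))
  m
}

# Small simulated cohort for fast pipeline tests.
small_sim <- function(seed = 42, ...) {
  simulate_cohort(cohort_params(n_genes = 250L, set_sizes = rep(12L, 10L),
                                n_patients = 12L,
                                samples_per_patient = c(2L, 3L),
                                seed = seed, ...))
}

# Brute-force running-sum oracle: explicit loop over partial sums.
walk_oracle <- function(in_set, d_in, d_out) {
  run <- 0
  pos <- -Inf
  neg <- Inf
  for (i in seq_along(in_set)) {
    run <- run + if (in_set[i]) d_in else d_out
    if (run > pos) pos <- run
    if (run < neg) neg <- run
  }
  list(positive = pos, negative = neg, total = pos - neg)
}

# Independent implementation of the dependent-correlation Z statistic,
# written directly from the published formula.
steiger_oracle_p <- function(r_jk, r_jh, r_kh, n) {
  zdiff <- atanh(r_jk) - atanh(r_jh)
  rb <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r_kh^2)
  cov <- psi / (1 - rb^2)^2
  z <- zdiff * sqrt((n - 3) / (2 - 2 * cov))
  stats::pnorm(z, lower.tail = FALSE)
}

# Trivariate normal sampler (no extra dependencies).
rmvnorm3 <- function(n, rho12, rho13, rho23) {
  Sg <- matrix(c(1, rho12, rho13,
                 rho12, 1, rho23,
                 rho13, rho23, 1), 3)
  matrix(stats::rnorm(3 * n), n) %*% chol(Sg)
}

# Exact expectation of the adjacency count over all distinct orderings of a
# label vector (exhaustive enumeration; use only for short vectors).
adjacency_expectation_exact <- function(labels) {
  count_adjacent <- function(lab) {
    n <- length(lab)
    left <- c(FALSE, lab[-1L] == lab[-n])
    right <- c(lab[-n] == lab[-1L], FALSE)
    sum(left | right)
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  mean(vapply(perms(labels), count_adjacent, numeric(1L)))
}

# Exact two-sided rank-sum p-value by exhausting group assignments.
ranksum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  obs <- sum(rank(pooled)[seq_len(k)])
  combos <- utils::combn(n, k)
  stats_all <- apply(combos, 2L, function(idx) sum(rank(pooled)[idx]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}

expect_warning_free <- function(expr) {
  expect_silent(suppressMessages(expr))
}
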