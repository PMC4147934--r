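#' Steiger's test of dependent (overlapping) correlations
#'
#' Tests whether one vector (here a sample signature) correlates more
#' strongly with reference k than with reference h, given that both
#' correlations share the sample vector. Both correlations are Fisher
#' z-transformed; their covariance is approximated with the
#' averaged-correlation form, using `r_bar = (r_jk + r_jh)/2`:
#'
#'   s = (r_kh (1 - 2 r_bar^2) - r_bar^2 (1 - 2 r_bar^2 - r_kh^2) / 2) /
#'       (1 - r_bar^2)^2
#'
#'   Z = sqrt(n - 3) (z_jk - z_jh) / sqrt(2 - 2 s)
#'
#' The one-sided p-value is the upper-tail normal probability of Z, i.e.
#' small p supports "j correlates better with k than with h". Z is
#' antisymmetric in (r_jk, r_jh), so swapping the two references maps p to
#' 1 - p, and equal correlations give Z = 0, p = 0.5 exactly.
#'
#' @param r_jk Correlation of the sample with reference k.
#' @param r_jh Correlation of the sample with reference h.
#' @param r_kh Correlation between the two references.
#' @param n Number of paired observations behind the correlations (here the
#'   number of gene sets, 15 in a typical signature); must be >= 4.
#' @param sided `"one"` (default, upper tail: r_jk > r_jh) or `"two"`.
#' @return List of class `steiger_result` with fields `r_jk`, `r_jh`,
#'   `r_kh`, `n`, `z_jk`, `z_jh`, `r_bar`, `s`, `Z`, `p`, `sided`.
#' @references Steiger, J.H. (1980) Tests for comparing elements of a
#'   correlation matrix. Psychological Bulletin 87, 245-251.
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n < 4L) stop("steiger_test requires n >= 4")
  for (r in c(r_jk, r_jh)) {
    if (!is.finite(r) || abs(r) >= 1)
      stop("correlations sharing the sample vector must lie strictly in (-1, 1)")
  }
  if (!is.finite(r_kh) || abs(r_kh) > 1)
    stop("reference-reference correlation must lie in [-1, 1]")
  z_jk <- atanh(r_jk)
  z_jh <- atanh(r_jh)
  r_bar <- (r_jk + r_jh) / 2
  s <- (r_kh * (1 - 2 * r_bar^2) -
          0.5 * r_bar^2 * (1 - 2 * r_bar^2 - r_kh^2)) / (1 - r_bar^2)^2
  if (2 - 2 * s <= 0)
    stop("degenerate covariance term (correlation triple not admissible)")
  Z <- sqrt(n - 3) * (z_jk - z_jh) / sqrt(2 - 2 * s)
  p <- if (sided == "one") {
    stats::pnorm(Z, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  }
  structure(list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n,
                 z_jk = z_jk, z_jh = z_jh, r_bar = r_bar, s = s,
                 Z = Z, p = p, sided = sided),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger dependent-correlation test (%s-sided, n = %d)\n",
              x$sided, x$n))
  cat(sprintf("  r_jk = %.4f, r_jh = %.4f, r_kh = %.4f\n",
              x$r_jk, x$r_jh, x$r_kh))
  cat(sprintf("  Z = %.4f, p = %.4g\n", x$Z, x$p))
  invisible(x)
}

# pairwise one-sided p-values p[k, h] = P-value for "r_k > r_h"
steiger_pairwise <- function(r, r_ref, n, sided = "one") {
  k <- length(r)
  p <- matrix(NA_real_, k, k, dimnames = list(names(r), names(r)))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      p[a, b] <- steiger_test(r[a], r[b], r_ref[a, b], n, sided)$p
    }
  }
  p
}

#' Exclusive subtype assignment
#'
#' Assigns a sample to the single subtype whose reference correlation is
#' significantly better than the correlation to every other subtype,
#' judged by one-sided [steiger_test()] p-values below `alpha`; otherwise
#' the sample is unassigned. At most one subtype can satisfy the criterion
#' for `alpha <= 0.5` because the pairwise p-values are antisymmetric
#' (p + p_swapped = 1).
#'
#' @param corrs Result of [correlate_to_references()] (fields `r`, `r_ref`,
#'   `n`), or a named correlation vector together with `r_ref` and `n`.
#' @param alpha Significance threshold in (0, 0.5].
#' @param r_ref,n Only needed when `corrs` is a bare vector.
#' @param sided Test sidedness, passed to [steiger_test()].
#' @return List of class `assignment_result` with `call` (a subtype name or
#'   `"unassigned"`), `mode = "exclusive"`, `alpha`, and the pairwise
#'   p-value matrix `pvalues`.
#' @export
assign_exclusive <- function(corrs, alpha = 0.05, r_ref = NULL, n = NULL,
                             sided = "one") {
  if (is.list(corrs)) {
    r <- corrs$r; r_ref <- corrs$r_ref; n <- corrs$n
  } else {
    r <- corrs
  }
  if (alpha <= 0 || alpha > 0.5) stop("alpha must lie in (0, 0.5]")
  p <- steiger_pairwise(r, r_ref, n, sided)
  winners <- which(apply(p, 1L, function(row) all(row[!is.na(row)] < alpha)))
  call <- if (length(winners) == 1L) names(r)[winners] else "unassigned"
  structure(list(call = call, mode = "exclusive", alpha = alpha,
                 pvalues = p, r = r, n = n),
            class = "assignment_result")
}

#' Prognosis-category assignment
#'
#' Combines the four subtypes into bad- and good-prognosis categories. A
#' sample is called `bad` if its correlation to at least one bad-prognosis
#' subtype is significantly better than its correlations to both
#' good-prognosis subtypes (the two bad subtypes need not differ from each
#' other); `good` by the mirrored rule; otherwise `unassigned`. For
#' `alpha <= 0.5` the two calls are mutually exclusive.
#'
#' @inheritParams assign_exclusive
#' @param bad,good Character vectors naming the bad- and good-prognosis
#'   subtypes (defaults: first two and last two reference rows).
#' @return List of class `assignment_result` with `call` in
#'   `c("bad", "good", "unassigned")` and the pairwise p-value matrix.
#' @export
assign_prognosis <- function(corrs, alpha = 0.05, bad = NULL, good = NULL,
                             r_ref = NULL, n = NULL, sided = "one") {
  if (is.list(corrs)) {
    r <- corrs$r; r_ref <- corrs$r_ref; n <- corrs$n
  } else {
    r <- corrs
  }
  if (alpha <= 0 || alpha > 0.5) stop("alpha must lie in (0, 0.5]")
  nm <- names(r)
  if (is.null(bad)) bad <- nm[1:2]
  if (is.null(good)) good <- setdiff(nm, bad)
  if (length(bad) != 2L || length(good) != 2L ||
      !all(c(bad, good) %in% nm) || length(intersect(bad, good)) > 0L)
    stop("need two disjoint bad- and two good-prognosis subtypes")
  p <- steiger_pairwise(r, r_ref, n, sided)
  beats_all <- function(x, others) all(p[x, others] < alpha)
  is_bad <- any(vapply(bad, beats_all, logical(1L), others = good))
  is_good <- any(vapply(good, beats_all, logical(1L), others = bad))
  if (is_bad && is_good)
    stop("bad and good conditions both hold; alpha > 0.5 is not meaningful")
  call <- if (is_bad) "bad" else if (is_good) "good" else "unassigned"
  structure(list(call = call, mode = "prognosis", alpha = alpha,
                 bad = bad, good = good, pvalues = p, r = r, n = n),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("Subtype assignment (%s mode, alpha = %g): %s\n",
              x$mode, x$alpha, x$call))
  invisible(x)
}

#' Tabulate assignment calls across thresholds and strata
#'
#' Counts calls per significance threshold, overall and stratified by sample
#' type, by bins of the normal-tissue fraction, and by Gleason group (6-7
#' versus 8-9) -- the three views typically shown for threshold sweeps.
#'
#' @param calls Data.frame with columns `sample_id`, `alpha`, `call` (one
#'   row per sample per threshold), e.g. the `assignments` element of a
#'   [fit_subtypes()] object.
#' @param metadata Sample metadata (see [read_sample_metadata()]); optional.
#'   Without it only the overall stratifier is produced.
#' @param frac_breaks Bin edges for `frac_normal`.
#' @return Data.frame with columns `stratifier`, `stratum`, `alpha`, `call`,
#'   `count`. An empty `calls` table gives zero counts.
#' @export
summarize_assignments <- function(calls, metadata = NULL,
                                  frac_breaks = seq(0, 1, by = 0.2)) {
  alphas <- sort(unique(calls$alpha))
  lvls <- sort(unique(calls$call))
  if (length(lvls) == 0L) lvls <- "unassigned"
  count_block <- function(df, stratifier, stratum) {
    if (nrow(df) == 0L && length(alphas) == 0L) {
      return(data.frame(stratifier = character(0), stratum = character(0),
                        alpha = numeric(0), call = character(0),
                        count = integer(0)))
    }
    grid <- expand.grid(alpha = alphas, call = lvls,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$count <- mapply(function(a, cl) {
      sum(df$alpha == a & df$call == cl)
    }, grid$alpha, grid$call)
    data.frame(stratifier = stratifier, stratum = stratum, grid,
               stringsAsFactors = FALSE)
  }
  out <- count_block(calls, "overall", "all")
  if (!is.null(metadata)) {
    md <- metadata[match(calls$sample_id, metadata$sample_id), , drop = FALSE]
    for (st in unique(md$sample_type)) {
      out <- rbind(out, count_block(calls[md$sample_type == st, , drop = FALSE],
                                    "sample_type", st))
    }
    fb <- cut(md$frac_normal, breaks = frac_breaks, include.lowest = TRUE)
    for (b in levels(fb)) {
      sel <- !is.na(fb) & fb == b & md$sample_type == "cancer"
      out <- rbind(out, count_block(calls[sel, , drop = FALSE],
                                    "frac_normal_bin", b))
    }
    gg <- ifelse(is.na(md$gleason), NA_character_,
                 ifelse(md$gleason <= 7L, "6-7", "8-9"))
    for (g in c("6-7", "8-9")) {
      sel <- !is.na(gg) & gg == g
      out <- rbind(out, count_block(calls[sel, , drop = FALSE],
                                    "gleason_group", g))
    }
  }
  rownames(out) <- NULL
  out
}
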