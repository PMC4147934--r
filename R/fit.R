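#' Fit signature-based subtype assignments for an expression cohort
#'
#' The front door of the package: runs the whole signature pipeline on an
#' expression cohort and returns a fitted object. The steps are
#' \enumerate{
#'   \item intersect the gene sets with the matrix genes,
#'   \item per-sample running-sum gene-set scores ([compute_raw_scores()]),
#'   \item optional averaging of related sets ([reduce_related_sets()]),
#'   \item normalization into sample signatures ([normalize_signatures()]),
#'   \item optional subtraction of the average normal signature scaled by
#'     each sample's normal-tissue fraction ([correct_cohort()]),
#'   \item Pearson correlation of each signature with the reference subtype
#'     profiles ([correlate_cohort()]),
#'   \item per-sample assignment at each threshold in `alpha` with the
#'     dependent-correlation test ([assign_exclusive()],
#'     [assign_prognosis()]).
#' }
#'
#' @param expr Expression matrix, genes x samples (log-scale values
#'   assumed).
#' @param gene_sets Named list of gene sets (see [read_gene_sets_gmt()]).
#' @param refs Reference subtype matrix, subtypes x gene sets (see
#'   [read_reference_matrix()] or [make_reference_from_truth()]).
#' @param metadata Optional sample metadata; required for the composition
#'   correction and for stratified summaries.
#' @param mapping Optional related-set grouping (named list) applied before
#'   normalization.
#' @param variant Walk weight variant, see [walk_weights()].
#' @param score_type `"signed"` (default) stores the dominant running-sum
#'   excursion with its sign, so depleted gene sets get low signature
#'   values; `"total"` stores the direction-blind `Score+ - Score-`, under
#'   which a strongly depleted set scores as high as an enriched one. The
#'   signed score is the default because the composition correction
#'   subtracts the normal signature directionally.
#' @param normalization Signature normalization mode, see
#'   [normalize_signatures()].
#' @param correct Subtract the normal-tissue component (needs `metadata`
#'   with at least one normal sample).
#' @param mode Assignment mode: `"prognosis"` (bad/good categories) or
#'   `"exclusive"` (single subtype).
#' @param bad,good Bad-/good-prognosis subtype names (prognosis mode);
#'   default: first two and last two rows of `refs`.
#' @param alpha Vector of significance thresholds in (0, 0.5].
#' @param sided Sidedness of the dependent-correlation test.
#' @param min_set_size Warn threshold for [intersect_gene_sets()].
#' @return Object of class `subtype_fit`; see Details. Methods: `print`,
#'   `summary`, `coef` (the signature matrix), `predict` (assign new
#'   samples against the same references), `plot` (clustered signature
#'   heatmap).
#' @examples
#' sim <- simulate_cohort(cohort_params(n_patients = 8, seed = 7))
#' refs <- make_reference_from_truth(sim)
#' fit <- fit_subtypes(sim$expr, sim$sets, refs, sim$metadata)
#' summary(fit)
#' @export
fit_subtypes <- function(expr, gene_sets, refs, metadata = NULL,
                         mapping = NULL,
                         variant = c("zero_sum_ks", "literal"),
                         score_type = c("signed", "total"),
                         normalization = "per_sample",
                         correct = !is.null(metadata),
                         mode = c("prognosis", "exclusive"),
                         bad = NULL, good = NULL,
                         alpha = c(0.05, 0.15, 0.25, 0.5),
                         sided = "one", min_set_size = 5L) {
  variant <- match.arg(variant)
  score_type <- match.arg(score_type)
  mode <- match.arg(mode)
  validate_expression_matrix(expr)
  validate_reference_matrix(refs)
  if (!is.null(metadata)) {
    metadata <- validate_sample_metadata(metadata)
    metadata <- match_metadata(expr, metadata)
  }
  sets <- intersect_gene_sets(gene_sets, rownames(expr), min_set_size)
  raw <- compute_raw_scores(expr, sets, variant,
                            signed = score_type == "signed")
  raw <- reduce_related_sets(raw, mapping)
  signatures <- normalize_signatures(raw, normalization)
  se_avg <- NULL
  corrected <- NULL
  if (correct) {
    if (is.null(metadata))
      stop("composition correction requires metadata")
    cc <- correct_cohort(signatures, metadata)
    corrected <- cc$corrected
    se_avg <- cc$se_avg
  }
  use_sig <- if (correct) corrected else signatures
  corrs <- correlate_cohort(use_sig, refs)
  assignments <- assign_cohort(corrs, mode = mode, bad = bad, good = good,
                               alpha = alpha, sided = sided)
  structure(list(raw_scores = raw, signatures = signatures,
                 corrected = corrected, se_avg = se_avg,
                 correlations = corrs, assignments = assignments,
                 refs = refs, metadata = metadata, mode = mode,
                 alpha = alpha, sided = sided, variant = variant,
                 score_type = score_type,
                 normalization = normalization, mapping = mapping,
                 gene_sets = sets, min_set_size = min_set_size,
                 bad = bad, good = good,
                 call = match.call()),
            class = "subtype_fit")
}

#' Assign every sample of a cohort at one or more thresholds
#'
#' @param corrs Result of [correlate_cohort()].
#' @param mode `"prognosis"` or `"exclusive"`.
#' @param bad,good Prognosis-category subtype names (prognosis mode).
#' @param alpha Vector of thresholds.
#' @param sided Test sidedness.
#' @return Data.frame with columns `sample_id`, `alpha`, `call`. Samples
#'   with undefined correlations are called `"unassigned"`.
#' @export
assign_cohort <- function(corrs, mode = c("prognosis", "exclusive"),
                          bad = NULL, good = NULL,
                          alpha = c(0.05, 0.15, 0.25, 0.5), sided = "one") {
  mode <- match.arg(mode)
  samples <- rownames(corrs$r)
  out <- expand.grid(sample_id = samples, alpha = alpha,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$call <- "unassigned"
  for (s in samples) {
    if (anyNA(corrs$r[s, ])) next
    one <- list(r = corrs$r[s, ], r_ref = corrs$r_ref, n = corrs$n[[s]])
    for (a in alpha) {
      res <- if (mode == "prognosis") {
        assign_prognosis(one, a, bad = bad, good = good, sided = sided)
      } else {
        assign_exclusive(one, a, sided = sided)
      }
      out$call[out$sample_id == s & out$alpha == a] <- res$call
    }
  }
  out
}

#' @export
print.subtype_fit <- function(x, ...) {
  n_samples <- ncol(x$signatures)
  cat(sprintf("Signature subtype fit: %d samples, %d gene sets, %d reference subtypes\n",
              n_samples, nrow(x$signatures), nrow(x$refs)))
  cat(sprintf("  walk: %s; normalization: %s; correction: %s; mode: %s (%s-sided)\n",
              x$variant, x$normalization,
              if (is.null(x$corrected)) "none" else "normal-component subtracted",
              x$mode, x$sided))
  for (a in x$alpha) {
    calls <- x$assignments$call[x$assignments$alpha == a]
    tab <- table(calls)
    cat(sprintf("  alpha = %-5g %s\n", a,
                paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.subtype_fit <- function(object, ...) {
  s <- summarize_assignments(object$assignments, object$metadata)
  structure(list(counts = s, alpha = object$alpha, mode = object$mode),
            class = "summary.subtype_fit")
}

#' @export
print.summary.subtype_fit <- function(x, ...) {
  cat(sprintf("Assignment counts (%s mode)\n", x$mode))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
coef.subtype_fit <- function(object, corrected = !is.null(object$corrected),
                             ...) {
  if (corrected) {
    if (is.null(object$corrected)) stop("fit has no corrected signatures")
    object$corrected
  } else {
    object$signatures
  }
}

#' Assign new samples against the references of an existing fit
#'
#' Scores a new expression matrix with the configuration stored in the fit
#' (same gene sets, walk variant, set grouping and normalization), applies
#' the stored average normal signature when the fit was
#' composition-corrected and metadata with tissue fractions is given, and
#' assigns each new sample against the same reference subtype matrix.
#' Mean-centering is performed within the new cohort, so single-sample
#' prediction is not supported.
#'
#' @param object A `subtype_fit`.
#' @param newdata Expression matrix, genes x new samples.
#' @param metadata Optional metadata for the new samples (needed for the
#'   composition correction).
#' @param alpha Threshold(s); defaults to those of the fit.
#' @param ... Unused.
#' @return Data.frame of calls, as in [assign_cohort()].
#' @export
predict.subtype_fit <- function(object, newdata, metadata = NULL,
                                alpha = object$alpha, ...) {
  validate_expression_matrix(newdata)
  sets <- intersect_gene_sets(object$gene_sets, rownames(newdata),
                              object$min_set_size)
  raw <- compute_raw_scores(newdata, sets, object$variant,
                            signed = object$score_type == "signed")
  raw <- reduce_related_sets(raw, object$mapping)
  sig <- normalize_signatures(raw, object$normalization)
  if (!is.null(object$se_avg) && !is.null(metadata)) {
    metadata <- validate_sample_metadata(metadata)
    md <- match_metadata(newdata, metadata)
    for (j in seq_len(ncol(sig))) {
      if (md$sample_type[j] == "cancer")
        sig[, j] <- subtract_normal_component(sig[, j], object$se_avg,
                                              md$frac_normal[j])
    }
  }
  corrs <- correlate_cohort(sig, object$refs)
  assign_cohort(corrs, mode = object$mode, bad = object$bad,
                good = object$good, alpha = alpha, sided = object$sided)
}

#' Clustered signature heatmap of a fit
#'
#' Displays the (corrected, if available) signature matrix with rows and
#' columns permuted into dendrogram leaf order from correlation-distance
#' hierarchical clustering, so similar samples and similar gene sets are
#' adjacent.
#'
#' @param x A `subtype_fit`.
#' @param linkage Linkage method, see [cluster_signatures()].
#' @param ... Passed to [graphics::image()].
#' @return The reordered signature matrix, invisibly.
#' @export
plot.subtype_fit <- function(x, linkage = "single", ...) {
  sig <- if (is.null(x$corrected)) x$signatures else x$corrected
  ord <- order_signature_matrix(sig, linkage)
  graphics::image(x = seq_len(ncol(ord)), y = seq_len(nrow(ord)),
                  z = t(ord), xlab = "samples (leaf order)",
                  ylab = "gene sets (leaf order)", axes = FALSE, ...)
  graphics::axis(2, at = seq_len(nrow(ord)), labels = rownames(ord),
                 las = 2, cex.axis = 0.6)
  graphics::box()
  invisible(ord)
}
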