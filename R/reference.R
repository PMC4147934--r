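#' Correlate one sample signature with the reference subtype profiles
#'
#' Pearson correlation of a sample's gene-set signature vector against each
#' row of the reference subtype matrix, computed over the gene sets shared
#' by both. Gene sets with missing (`NA`) signature values are dropped from
#' all correlations for that sample with a warning; fewer than 4 surviving
#' gene sets, or a constant signature, make the correlations (and the
#' downstream dependent-correlation test) undefined, and raise an error of
#' class `prosig_unassignable` so cohort drivers can record the sample as
#' unassignable rather than abort.
#'
#' @param sig Named numeric vector (one value per gene set).
#' @param refs Reference matrix, subtypes x gene sets (see
#'   [read_reference_matrix()]).
#' @return List with `r` (named correlation per subtype), `r_ref` (subtype x
#'   subtype correlation matrix of the references themselves), and `n` (the
#'   number of gene sets entering the correlations).
#' @export
correlate_to_references <- function(sig, refs) {
  if (is.null(names(sig))) stop("signature vector must be named by gene set")
  miss <- setdiff(colnames(refs), names(sig))
  if (length(miss) > 0L)
    stop("signature lacks reference gene set(s): ", paste(miss, collapse = ", "))
  sig <- sig[colnames(refs)]
  keep <- !is.na(sig)
  if (!all(keep)) {
    warning("dropping gene set(s) with undefined scores: ",
            paste(colnames(refs)[!keep], collapse = ", "))
  }
  n <- sum(keep)
  if (n < 4L)
    stop(unassignable_error("fewer than 4 gene sets with defined scores"))
  v <- sig[keep]
  if (stats::sd(v) == 0)
    stop(unassignable_error("constant signature (correlation undefined)"))
  sub <- refs[, keep, drop = FALSE]
  if (any(apply(sub, 1L, stats::sd) == 0))
    stop("reference row constant over the surviving gene sets")
  r <- as.vector(stats::cor(v, t(sub)))
  names(r) <- rownames(refs)
  list(r = r, r_ref = inter_reference_correlations(refs, keep), n = n)
}

#' Subtype-by-subtype correlations of the reference profiles
#'
#' @param refs Reference matrix, subtypes x gene sets.
#' @param keep Optional logical mask of gene-set columns to use.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
inter_reference_correlations <- function(refs, keep = NULL) {
  if (!is.null(keep)) refs <- refs[, keep, drop = FALSE]
  stats::cor(t(refs))
}

#' Correlate every sample of a signature matrix with the references
#'
#' Cohort wrapper around [correlate_to_references()]. Samples whose
#' correlations are undefined (constant signature or too few gene sets) get
#' `NA` correlations and are flagged, with a warning, instead of aborting
#' the cohort.
#'
#' @param sig Signature matrix, gene sets x samples.
#' @param refs Reference matrix, subtypes x gene sets.
#' @return List with `r` (samples x subtypes correlation matrix), `r_ref`,
#'   `n` (per-sample gene-set count), and `unassignable` (character vector
#'   of sample ids).
#' @export
correlate_cohort <- function(sig, refs) {
  samples <- colnames(sig)
  r <- matrix(NA_real_, length(samples), nrow(refs),
              dimnames = list(samples, rownames(refs)))
  n <- setNames(rep(NA_integer_, length(samples)), samples)
  bad <- character(0)
  for (s in samples) {
    res <- tryCatch(correlate_to_references(sig[, s], refs),
                    prosig_unassignable = function(e) NULL)
    if (is.null(res)) {
      bad <- c(bad, s)
    } else {
      r[s, ] <- res$r
      n[s] <- res$n
    }
  }
  if (length(bad) > 0L)
    warning("unassignable sample(s) (undefined correlations): ",
            paste(bad, collapse = ", "))
  list(r = r, r_ref = inter_reference_correlations(refs), n = n,
       unassignable = bad)
}

unassignable_error <- function(msg) {
  structure(class = c("prosig_unassignable", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
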