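#' Average normal-tissue signature
#'
#' Element-wise mean of the signatures of all normal samples; this is the
#' profile subtracted from cancer samples to emphasize their cancer
#' component.
#'
#' @param normal_sigs Signature matrix, gene sets x normal samples (one
#'   column suffices).
#' @return Named numeric vector with attribute `n_normals`.
#' @export
average_normal_signature <- function(normal_sigs) {
  if (is.null(dim(normal_sigs)))
    normal_sigs <- matrix(normal_sigs, ncol = 1L,
                          dimnames = list(names(normal_sigs), "normal"))
  if (ncol(normal_sigs) < 1L) stop("need at least one normal signature")
  avg <- rowMeans(normal_sigs)
  attr(avg, "n_normals") <- ncol(normal_sigs)
  avg
}

#' Subtract the normal-tissue component from one signature
#'
#' Applies the composition correction
#' `corrected = PR - SE_AVG * frac / (1 - frac)`, where `PR` is the sample's
#' signature, `SE_AVG` the average normal signature and `frac` the fraction
#' of normal tissue in the sample from histopathology. A higher fraction
#' subtracts more of the normal signature (frac = 0.5 subtracts it once;
#' frac = 0.9 subtracts it nine-fold). The correction is exactly the
#' algebraic inverse of the additive contamination model
#' `PR_obs = PR_true + SE_AVG * frac / (1 - frac)`. Corrected values may
#' leave `[0, 1]` and are deliberately not renormalized, preserving
#' inter-sample comparability.
#'
#' @param pr Named numeric signature vector.
#' @param se_avg Average normal signature (same gene sets, same order).
#' @param frac Fraction of normal tissue in `[0, 0.95]`; values above 0.95
#'   (near-pure normal "cancer" samples) are refused because the factor
#'   `frac/(1-frac)` diverges.
#' @return Corrected signature vector.
#' @export
subtract_normal_component <- function(pr, se_avg, frac) {
  if (length(pr) != length(se_avg))
    stop("signature and average normal signature differ in length")
  if (!is.finite(frac) || frac < 0)
    stop("frac must be a fraction in [0, 0.95]")
  if (frac >= 1) stop("frac >= 1: correction undefined (division by zero)")
  if (frac > 0.95) stop("frac > 0.95: subtraction factor too extreme")
  pr - se_avg * frac / (1 - frac)
}

#' Composition-correct a cohort of signatures
#'
#' Computes the average normal signature from the normal samples of the
#' cohort and subtracts each cancer sample's normal component scaled by its
#' own histological normal-tissue fraction. Normal samples pass through
#' unchanged unless `include_normals = TRUE`, in which case they are
#' corrected at `normal_frac` (default 0.9, the strongest factor in use) --
#' the control analysis that checks the subtraction does not manufacture
#' cancer signatures in normal tissue.
#'
#' @param sig Signature matrix, gene sets x samples.
#' @param metadata Metadata covering every sample (see
#'   [read_sample_metadata()]).
#' @param include_normals Also correct normal samples at `normal_frac`.
#' @param normal_frac Fraction used for normal samples when
#'   `include_normals = TRUE`.
#' @return List with `corrected` (matrix, same shape as `sig`) and `se_avg`
#'   (the average normal signature used).
#' @export
correct_cohort <- function(sig, metadata, include_normals = FALSE,
                           normal_frac = 0.9) {
  md <- metadata[match(colnames(sig), metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id)))
    stop("metadata missing for sample(s): ",
         paste(colnames(sig)[is.na(md$sample_id)], collapse = ", "))
  normals <- md$sample_type == "normal"
  if (!any(normals))
    stop("no normal samples: average normal signature undefined")
  se_avg <- average_normal_signature(sig[, normals, drop = FALSE])
  cancers <- which(!normals)
  no_frac <- cancers[is.na(md$frac_normal[cancers])]
  if (length(no_frac) > 0L)
    stop("cancer sample(s) without frac_normal: ",
         paste(md$sample_id[no_frac], collapse = ", "))
  out <- sig
  for (j in cancers) {
    out[, j] <- subtract_normal_component(sig[, j], se_avg,
                                          md$frac_normal[j])
  }
  if (include_normals) {
    for (j in which(normals)) {
      out[, j] <- subtract_normal_component(sig[, j], se_avg, normal_frac)
    }
  }
  list(corrected = out, se_avg = se_avg)
}
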