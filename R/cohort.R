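#' Pairwise Pearson correlations between sample signatures
#'
#' @param sig Signature matrix, gene sets x samples (at least 2 samples).
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal. A constant signature column is an error naming the sample.
#' @export
pairwise_signature_correlations <- function(sig) {
  if (ncol(sig) < 2L) stop("need at least 2 samples")
  sds <- apply(sig, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant signature(s), correlation undefined: ",
         paste(colnames(sig)[sds == 0], collapse = ", "))
  stats::cor(sig)
}

#' Split pairwise correlations into within-group and between-group sets
#'
#' Four groupings are supported, each defining which unordered sample pairs
#' count as "within" and which as "between":
#' \describe{
#'   \item{patient}{cancer samples only; within = same patient, between =
#'     different patients.}
#'   \item{gleason}{cancer samples with a Gleason score; within = same
#'     score, between = different scores.}
#'   \item{sample_type}{all samples; within = cancer-cancer and
#'     normal-normal pairs, between = cancer-normal pairs.}
#'   \item{normal_vs_cancer_patient}{normal-cancer pairs only; within =
#'     same patient, between = different patients.}
#' }
#' The within/between sets are disjoint and exhaust the eligible pairs. The
#' comparison p-value comes from [compare_groups()].
#'
#' @param corr Samples x samples correlation matrix (see
#'   [pairwise_signature_correlations()]).
#' @param metadata Metadata covering the samples.
#' @param grouping One of the groupings above.
#' @return List of class `group_correlation_report` with `grouping`,
#'   `within_values`, `between_values`, `within_median`, `between_median`,
#'   `p`.
#' @export
within_between_split <- function(corr, metadata,
                                 grouping = c("patient", "gleason",
                                              "sample_type",
                                              "normal_vs_cancer_patient")) {
  grouping <- match.arg(grouping)
  ids <- colnames(corr)
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (any(is.na(md$sample_id)))
    stop("metadata missing for sample(s): ",
         paste(ids[is.na(md$sample_id)], collapse = ", "))
  within <- numeric(0)
  between <- numeric(0)
  n <- length(ids)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      v <- corr[a, b]
      if (grouping == "patient") {
        if (md$sample_type[a] != "cancer" || md$sample_type[b] != "cancer")
          next
        if (md$patient_id[a] == md$patient_id[b]) within <- c(within, v)
        else between <- c(between, v)
      } else if (grouping == "gleason") {
        if (md$sample_type[a] != "cancer" || md$sample_type[b] != "cancer")
          next
        if (is.na(md$gleason[a]) || is.na(md$gleason[b])) next
        if (md$gleason[a] == md$gleason[b]) within <- c(within, v)
        else between <- c(between, v)
      } else if (grouping == "sample_type") {
        if (md$sample_type[a] == md$sample_type[b]) within <- c(within, v)
        else between <- c(between, v)
      } else {
        ta <- md$sample_type[a]; tb <- md$sample_type[b]
        if (ta == tb) next
        if (md$patient_id[a] == md$patient_id[b]) within <- c(within, v)
        else between <- c(between, v)
      }
    }
  }
  if (length(within) == 0L)
    stop("no within-group pairs for grouping '", grouping, "'")
  if (length(between) == 0L)
    stop("no between-group pairs for grouping '", grouping, "'")
  structure(list(grouping = grouping,
                 within_values = within, between_values = between,
                 within_median = stats::median(within),
                 between_median = stats::median(between),
                 p = compare_groups(within, between)),
            class = "group_correlation_report")
}

#' @export
print.group_correlation_report <- function(x, ...) {
  cat(sprintf("Signature correlations, grouping = %s\n", x$grouping))
  cat(sprintf("  within:  n = %4d, median r = %.3f\n",
              length(x$within_values), x$within_median))
  cat(sprintf("  between: n = %4d, median r = %.3f\n",
              length(x$between_values), x$between_median))
  cat(sprintf("  rank-sum p = %.3g\n", x$p))
  invisible(x)
}

#' Compare two sets of correlations
#'
#' Two-sided Mann-Whitney rank-sum comparison of the within-group and
#' between-group correlation values; correlations are bounded and skewed, so
#' a rank-based test is used rather than a t-test.
#'
#' @param within_values,between_values Non-empty numeric vectors.
#' @return The two-sided p-value.
#' @export
compare_groups <- function(within_values, between_values) {
  if (length(within_values) == 0L || length(between_values) == 0L)
    stop("both groups must be non-empty")
  stats::wilcox.test(within_values, between_values,
                     alternative = "two.sided", exact = NULL)$p.value
}

#' Hierarchical clustering of sample signatures
#'
#' Agglomerative clustering with correlation distance `1 - r` between
#' sample signatures (or between gene sets with `margin = "sets"`). The
#' default linkage is single, and the dendrogram's left-to-right leaf order
#' is returned for ordering exported matrices so that similar samples sit
#' next to each other.
#'
#' @param sig Signature matrix, gene sets x samples.
#' @param linkage Linkage method for [stats::hclust()].
#' @param margin Cluster `"samples"` (columns, default) or `"sets"` (rows).
#' @return List of class `signature_clustering` with `hclust` (the merge
#'   tree), `leaf_order` (ids in dendrogram order), `linkage`, `margin`.
#' @export
cluster_signatures <- function(sig,
                               linkage = c("single", "average", "complete",
                                           "ward.D2"),
                               margin = c("samples", "sets")) {
  linkage <- match.arg(linkage)
  margin <- match.arg(margin)
  m <- if (margin == "samples") sig else t(sig)
  if (ncol(m) < 2L) stop("need at least 2 items to cluster")
  corr <- pairwise_signature_correlations(m)
  hc <- stats::hclust(stats::as.dist(1 - corr), method = linkage)
  structure(list(hclust = hc, leaf_order = colnames(m)[hc$order],
                 linkage = linkage, margin = margin),
            class = "signature_clustering")
}

#' @export
print.signature_clustering <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d %s (1 - Pearson r, %s linkage)\n",
              length(x$leaf_order), x$margin, x$linkage))
  invisible(x)
}

#' Reorder a signature matrix by clustering in both directions
#'
#' @param sig Signature matrix, gene sets x samples.
#' @param linkage Linkage method, see [cluster_signatures()].
#' @return `sig` with rows and columns permuted into dendrogram leaf order.
#' @export
order_signature_matrix <- function(sig, linkage = "single") {
  cs <- cluster_signatures(sig, linkage, "samples")$leaf_order
  rs <- cluster_signatures(sig, linkage, "sets")$leaf_order
  sig[rs, cs, drop = FALSE]
}

#' Same-patient cluster-neighbor statistic
#'
#' Counts how many samples sit immediately next to (left or right of) a
#' sample from the same patient in the dendrogram leaf order, and compares
#' the count with its permutation null: the patient labels are kept fixed
#' and positions are shuffled uniformly. The expected count is the mean over
#' permutations and the p-value is the add-one-smoothed upper-tail
#' fraction.
#'
#' @param labels Patient labels in dendrogram leaf order (length >= 2).
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Optional integer seed.
#' @return List with `observed`, `expected`, `p`, `n_perm`.
#' @export
neighbor_same_patient_stat <- function(labels, n_perm = 10000L, seed = NULL) {
  if (length(labels) < 2L) stop("need at least 2 leaves")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  count_adjacent <- function(lab) {
    n <- length(lab)
    left <- c(FALSE, lab[-1L] == lab[-n])
    right <- c(lab[-n] == lab[-1L], FALSE)
    sum(left | right)
  }
  obs <- count_adjacent(labels)
  perm <- vapply(seq_len(n_perm),
                 function(i) count_adjacent(sample(labels)), numeric(1L))
  list(observed = obs, expected = mean(perm),
       p = (1 + sum(perm >= obs)) / (n_perm + 1), n_perm = n_perm)
}
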