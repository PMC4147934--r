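#' Running-sum walk weights
#'
#' Increments for the Kolmogorov-Smirnov-style running sum over a ranked
#' gene list. Two variants are provided. `zero_sum_ks` (the default used
#' throughout the package) uses `d_in = sqrt((N-S)/S)` for in-set genes and
#' `d_out = -sqrt(S/(N-S))` otherwise, so that the partial sum returns to 0
#' at the end of the list; the running-sum maximum and minimum then measure
#' enrichment at the top and bottom of the ranking. The `literal` variant
#' uses `d_in = (N-S)/S`, `d_out = -S/(N-S)`; its walk terminates at `N-2S`
#' rather than 0, which inflates apparent enrichment of small sets, so it is
#' retained only as an explicit option.
#'
#' @param n Total number of scored genes (N).
#' @param s Number of in-set genes (S), with `1 <= s < n`.
#' @param variant One of `"zero_sum_ks"` or `"literal"`.
#' @return List with elements `d_in`, `d_out`, `n`, `s`, `variant`.
#' @export
walk_weights <- function(n, s, variant = c("zero_sum_ks", "literal")) {
  variant <- match.arg(variant)
  n <- as.integer(n); s <- as.integer(s)
  if (n < 2L) stop("need at least 2 genes")
  if (s < 1L || s >= n) stop("set size S must satisfy 1 <= S < N")
  if (variant == "zero_sum_ks") {
    list(d_in = sqrt((n - s) / s), d_out = -sqrt(s / (n - s)),
         n = n, s = s, variant = variant)
  } else {
    list(d_in = (n - s) / s, d_out = -s / (n - s),
         n = n, s = s, variant = variant)
  }
}

#' Single gene-set running-sum walk
#'
#' Walks down a ranked gene list, adding `d_in` when the gene belongs to the
#' set and `d_out` otherwise, and records the running-sum extremes:
#' `positive` (Score+) is the maximum partial sum, `negative` (Score-) the
#' minimum, and `total = positive - negative`. A set concentrated at the top
#' of the ranking drives Score+ up; a set concentrated at the bottom drives
#' Score- down. The total is symmetric in the two (a strongly depleted set
#' scores as high as a strongly enriched one); `signed = TRUE` instead
#' returns whichever of Score+ and |Score-| is larger, with its sign, for
#' direction-sensitive analyses.
#'
#' @param in_set Logical vector along the ranked gene list (`TRUE` = gene is
#'   in the set), ordered from the top-ranked gene down.
#' @param variant Weight variant, see [walk_weights()].
#' @param signed If `TRUE`, `total` is the signed dominant excursion rather
#'   than `positive - negative`.
#' @return List with `positive`, `negative`, `total`.
#' @export
gsea_walk <- function(in_set, variant = c("zero_sum_ks", "literal"),
                      signed = FALSE) {
  variant <- match.arg(variant)
  if (!is.logical(in_set)) stop("in_set must be a logical vector")
  n <- length(in_set)
  s <- sum(in_set)
  w <- walk_weights(n, s, variant)
  steps <- ifelse(in_set, w$d_in, w$d_out)
  cs <- cumsum(steps)
  pos <- max(cs)
  neg <- min(cs)
  total <- if (signed) {
    if (pos >= -neg) pos else neg
  } else {
    pos - neg
  }
  list(positive = pos, negative = neg, total = total)
}

#' Per-sample raw gene-set scores for a cohort
#'
#' For each sample: every gene is first mean-centered across all samples of
#' the matrix, the sample's centered values are sorted in descending order
#' (ties broken by input gene order, so results are deterministic), and the
#' running-sum walk of [gsea_walk()] is evaluated for every gene set. The
#' stored value is the total score.
#'
#' @param expr Expression matrix, genes x samples (see
#'   [validate_expression_matrix()]).
#' @param sets Named list of gene sets, already intersected with
#'   `rownames(expr)` (see [intersect_gene_sets()]).
#' @param variant Walk weight variant.
#' @param signed Use the signed dominant-excursion total (see [gsea_walk()]).
#' @return Numeric matrix, gene sets x samples, of total scores.
#' @export
compute_raw_scores <- function(expr, sets, variant = c("zero_sum_ks", "literal"),
                               signed = FALSE) {
  variant <- match.arg(variant)
  validate_expression_matrix(expr)
  if (length(sets) == 0L) stop("empty gene set collection")
  genes <- rownames(expr)
  membership <- lapply(sets, function(g) genes %in% g)
  sizes <- vapply(membership, sum, integer(1L))
  if (any(sizes == 0L))
    stop("gene set(s) share no genes with the matrix: ",
         paste(names(sets)[sizes == 0L], collapse = ", "))
  if (any(sizes >= length(genes)))
    stop("gene set(s) cover all scored genes: ",
         paste(names(sets)[sizes >= length(genes)], collapse = ", "))
  centered <- expr - rowMeans(expr)
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(centered[, j], decreasing = TRUE, method = "radix")
    for (i in seq_along(sets)) {
      out[i, j] <- gsea_walk(membership[[i]][ord], variant, signed)$total
    }
  }
  out
}

#' Average scores over groups of related gene sets
#'
#' Reduces a raw score matrix by replacing each named group of related sets
#' with the arithmetic mean of their score rows. Ungrouped sets pass through
#' unchanged, after the grouped rows.
#'
#' @param raw Score matrix, gene sets x samples.
#' @param mapping Named list: each element is a character vector of set names
#'   to average; the element name is the name of the reduced set. A set may
#'   appear in at most one group.
#' @return Reduced score matrix.
#' @export
reduce_related_sets <- function(raw, mapping) {
  if (is.null(mapping) || length(mapping) == 0L) return(raw)
  members <- unlist(mapping, use.names = FALSE)
  unknown <- setdiff(members, rownames(raw))
  if (length(unknown) > 0L)
    stop("mapping references unknown gene set(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(members))
    stop("gene set(s) assigned to more than one group: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  grouped <- do.call(rbind, lapply(mapping, function(g) {
    colMeans(raw[g, , drop = FALSE])
  }))
  rownames(grouped) <- names(mapping)
  rest <- setdiff(rownames(raw), members)
  out <- rbind(grouped, raw[rest, , drop = FALSE])
  colnames(out) <- colnames(raw)
  out
}

minmax01 <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NULL)  # caller handles the constant case
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Normalize raw gene-set scores into sample signatures
#'
#' Three strategies are supported. `per_sample` (the default) rescales each
#' sample's scores linearly onto `[0,1]`, so signatures of new samples are
#' comparable without re-normalizing a whole cohort; `per_set` rescales each
#' gene set's scores across samples instead; `random_set_pvalue` converts
#' each score into an empirical p-value against `B` random gene sets of the
#' same size drawn from the scored genes, with add-one smoothing so p is
#' never 0. A constant column (per_sample) or row (per_set) is mapped to 0.5
#' with a warning rather than aborting the cohort; downstream correlation
#' then fails explicitly for such degenerate signatures.
#'
#' @param raw Score matrix, gene sets x samples.
#' @param mode Normalization strategy, see above.
#' @param expr,sets Required for `random_set_pvalue`: the expression matrix
#'   the scores came from and the (intersected) gene sets, used to size the
#'   random sets.
#' @param B Number of random sets per set size (`random_set_pvalue`).
#' @param variant,signed Walk options, must match those used for `raw`.
#' @param seed Optional integer seed for the random sets.
#' @return Matrix of the same shape as `raw` with a `normalization_mode`
#'   attribute.
#' @export
normalize_signatures <- function(raw,
                                 mode = c("per_sample", "per_set",
                                          "random_set_pvalue"),
                                 expr = NULL, sets = NULL, B = 99L,
                                 variant = c("zero_sum_ks", "literal"),
                                 signed = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (any(!is.finite(raw))) stop("raw scores must be finite")
  out <- raw
  if (mode == "per_sample") {
    for (j in seq_len(ncol(raw))) {
      v <- minmax01(raw[, j])
      if (is.null(v)) {
        warning("constant score column for sample '", colnames(raw)[j],
                "'; normalized values set to 0.5")
        v <- rep(0.5, nrow(raw))
      }
      out[, j] <- v
    }
  } else if (mode == "per_set") {
    for (i in seq_len(nrow(raw))) {
      v <- minmax01(raw[i, ])
      if (is.null(v)) {
        warning("constant score row for gene set '", rownames(raw)[i],
                "'; normalized values set to 0.5")
        v <- rep(0.5, ncol(raw))
      }
      out[i, ] <- v
    }
  } else {
    if (is.null(expr) || is.null(sets))
      stop("random_set_pvalue normalization needs expr and sets")
    if (!all(rownames(raw) %in% names(sets)))
      stop("raw rows must match the supplied gene sets")
    if (!is.null(seed)) set.seed(seed)
    genes <- rownames(expr)
    sizes <- vapply(sets[rownames(raw)], length, integer(1L))
    null_by_size <- list()
    for (s in unique(sizes)) {
      rand_sets <- lapply(seq_len(B), function(b) sample(genes, s))
      names(rand_sets) <- paste0("rand", seq_len(B))
      null_by_size[[as.character(s)]] <-
        compute_raw_scores(expr, rand_sets, variant, signed)
    }
    for (i in seq_len(nrow(raw))) {
      null_scores <- null_by_size[[as.character(sizes[i])]]
      for (j in seq_len(ncol(raw))) {
        out[i, j] <- (1 + sum(null_scores[, j] >= raw[i, j])) / (B + 1)
      }
    }
  }
  attr(out, "normalization_mode") <- mode
  out
}
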