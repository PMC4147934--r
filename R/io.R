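#' Read a gene expression matrix from a tab-separated file
#'
#' The file must have sample identifiers in the first (header) row and gene
#' identifiers in the first column; the body must be numeric (log-scale
#' expression values are assumed but not enforced). Row and column order are
#' preserved.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with unique row and column names.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L)
    stop("expression file needs a gene-id column plus at least one sample column")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("non-numeric or non-finite value '%s' at gene '%s' (row %d), sample '%s' (column %d)",
                 body[i, j], gene_ids[i], i, sample_ids[j], j))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  validate_expression_matrix(num)
  num
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the package: unique gene and
#' sample identifiers, finite numeric values, at least 2 genes and 1 sample.
#'
#' @param x A numeric matrix with gene row names and sample column names.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene row names and sample column names")
  if (nrow(x) < 2L || ncol(x) < 1L)
    stop("expression matrix needs at least 2 genes and 1 sample")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup) > 0L)
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup) > 0L)
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; the first column is named `gene_id`.
#'
#' @param x Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, and one or more gene
#' identifiers, tab-separated. Gene identifiers are matched downstream as
#' exact case-sensitive strings. Duplicate genes within a set are removed
#' with a warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one element per gene set).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d ('%s') has no genes", i, f[1L]))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("GMT line %d ('%s') has no genes", i, f[1L]))
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s' lists duplicate genes; duplicates removed", f[1L]))
      genes <- unique(genes)
    }
    nms[i] <- f[1L]
    sets[[i]] <- genes
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0L)
    stop("duplicate gene set name(s): ", paste(dup, collapse = ", "))
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample metadata from a tab-separated file
#'
#' Expected columns: `sample_id`, `patient_id`, `sample_type` (one of
#' `cancer`/`normal`), `gleason` (integer 6-10, may be blank for normal
#' samples), and `frac_normal` (fraction of normal tissue in `[0,1]`;
#' alternatively a `percent_cancer` column in `[0,100]` is accepted and
#' converted via `frac_normal = 1 - percent_cancer/100`). Normal samples with
#' missing `frac_normal` are assigned 1 by convention. A cancer sample with
#' missing Gleason score is retained with a warning.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with the columns above.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' Validate (and normalize) a sample metadata table
#'
#' @param df A data.frame with the columns documented in
#'   [read_sample_metadata()].
#' @return The validated data.frame (with `percent_cancer` converted to
#'   `frac_normal` when necessary).
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample_id", "patient_id", "sample_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!"frac_normal" %in% colnames(df)) {
    if ("percent_cancer" %in% colnames(df)) {
      pc <- as.numeric(df$percent_cancer)
      if (any(!is.na(pc) & (pc < 0 | pc > 100)))
        stop("percent_cancer outside [0, 100]")
      df$frac_normal <- 1 - pc / 100
    } else {
      stop("metadata needs a frac_normal (or percent_cancer) column")
    }
  }
  if (!"gleason" %in% colnames(df)) df$gleason <- NA_integer_
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L)
    stop("duplicate sample_id(s) in metadata: ", paste(dup, collapse = ", "))
  if (!all(df$sample_type %in% c("cancer", "normal")))
    stop("sample_type must be 'cancer' or 'normal'")
  df$frac_normal <- as.numeric(df$frac_normal)
  df$frac_normal[df$sample_type == "normal" & is.na(df$frac_normal)] <- 1
  bad <- !is.na(df$frac_normal) & (df$frac_normal < 0 | df$frac_normal > 1)
  if (any(bad))
    stop("frac_normal outside [0, 1] for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  gl <- suppressWarnings(as.integer(df$gleason))
  if (any(!is.na(gl) & (gl < 6L | gl > 10L)))
    stop("gleason scores must be integers in 6..10")
  df$gleason <- gl
  no_gl <- df$sample_type == "cancer" & is.na(df$gleason)
  if (any(no_gl))
    warning("cancer sample(s) without Gleason score retained: ",
            paste(df$sample_id[no_gl], collapse = ", "))
  df
}

#' Check that metadata covers an expression matrix one-to-one
#'
#' Every sample column of `expr` must have exactly one metadata record.
#'
#' @param expr Expression matrix (genes x samples).
#' @param metadata Metadata data.frame (see [read_sample_metadata()]).
#' @return The metadata rows matching `expr`, in `expr` column order.
#' @export
match_metadata <- function(expr, metadata) {
  miss <- setdiff(colnames(expr), metadata$sample_id)
  if (length(miss) > 0L)
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  metadata[match(colnames(expr), metadata$sample_id), , drop = FALSE]
}

#' Write sample metadata as TSV
#' @param df Metadata data.frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference subtype signature matrix from TSV
#'
#' Rows are subtypes, columns are (reduced) gene sets, values must lie in
#' `[-1, 1]`. Rows typically encode a visual digitization of published
#' subtype heatmaps (e.g. values in \{-1, -0.5, 0, 0.5, 1\}). A constant row
#' is rejected because Pearson correlation against it is undefined.
#'
#' @param path Path to a TSV file (first column = subtype names).
#' @return Numeric matrix, subtypes x gene sets.
#' @export
read_reference_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 3L)
    stop("reference matrix needs a subtype column plus at least 2 gene-set columns")
  subtypes <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric reference value '%s' at row %d, column %d",
                 body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  dimnames(num) <- list(subtypes, colnames(df)[-1L])
  validate_reference_matrix(num)
  num
}

#' Validate a reference subtype matrix
#' @param x Numeric matrix, subtypes x gene sets.
#' @return `x`, invisibly, if valid.
#' @export
validate_reference_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("reference must be a numeric matrix")
  if (anyDuplicated(rownames(x))) stop("duplicate subtype names in reference")
  if (anyDuplicated(colnames(x))) stop("duplicate gene-set names in reference")
  if (any(x < -1 | x > 1))
    stop("reference values must lie in [-1, 1]")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant reference row(s) (correlation undefined): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  invisible(x)
}

#' Write a reference subtype matrix as TSV
#' @param x Numeric matrix, subtypes x gene sets.
#' @param path Output path.
#' @export
write_reference_matrix <- function(x, path) {
  df <- data.frame(subtype = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect gene sets with the genes of an expression matrix
#'
#' Gene sets are restricted to genes present in the matrix before scoring.
#' Sets retaining fewer than `min_size` genes trigger a warning (scores from
#' very small sets are fragile); sets retaining no genes at all are dropped
#' with a warning.
#'
#' @param sets Named list of character vectors.
#' @param genes Character vector of gene identifiers (e.g. `rownames(expr)`).
#' @param min_size Minimum retained size below which a warning is emitted.
#' @return The intersected collection (possibly with sets dropped).
#' @export
intersect_gene_sets <- function(sets, genes, min_size = 5L) {
  out <- lapply(sets, function(g) g[g %in% genes])
  sizes <- lengths(out)
  if (any(sizes == 0L)) {
    warning("gene set(s) with no genes in the matrix dropped: ",
            paste(names(out)[sizes == 0L], collapse = ", "))
    out <- out[sizes > 0L]
    sizes <- lengths(out)
  }
  small <- sizes < min_size
  if (any(small))
    warning("gene set(s) retain fewer than ", min_size, " genes: ",
            paste(sprintf("%s (%d)", names(out)[small], sizes[small]),
                  collapse = ", "))
  if (any(sizes >= length(genes)))
    stop("gene set(s) cover every scored gene (walk undefined): ",
         paste(names(out)[sizes >= length(genes)], collapse = ", "))
  out
}
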