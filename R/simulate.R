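#' Subtype names used by the synthetic cohort generator
#'
#' Two bad-prognosis subtypes (an embryonic-stem-cell/PTEN-loss/
#' proliferation-like program and an ERG-fusion-like program) and two
#' good-prognosis subtypes.
#' @export
PROSIG_SUBTYPES <- c("BP-E/P/Pr", "BP-ERG", "GP1", "GP2")

#' Parameters for a synthetic expression cohort
#'
#' Bundles and validates every knob of the generator. The defaults emulate
#' a prostatectomy cohort of roughly 150 samples from 40 patients with
#' repeated sampling per patient, a quarter of samples being pure normal
#' tissue, latent subtype structure expressed as mean shifts on
#' subtype-characteristic gene sets, a shared per-patient expression shift,
#' linear cancer/normal tissue mixing, and unit-variance gene-level noise.
#'
#' @param n_genes Size of the gene universe.
#' @param set_sizes Integer vector of gene-set sizes (one set each).
#' @param overlap_fraction Fraction of each set drawn from genes already
#'   used by earlier sets (0 = disjoint sets).
#' @param n_patients Number of patients.
#' @param samples_per_patient Length-2 integer range; each patient
#'   contributes a uniform draw from it.
#' @param subtype_prevalences Named probabilities over
#'   [PROSIG_SUBTYPES], summing to 1.
#' @param effect_size Mean expression shift (in units of `noise_sd`) applied
#'   to genes of the sample subtype's characteristic sets.
#' @param patient_effect_sd SD of the per-patient gene-level Gaussian shift
#'   shared by all of a patient's cancer samples.
#' @param noise_sd SD of the i.i.d. per-gene measurement noise.
#' @param normal_profile_sd SD of the unstructured gene-level part of the
#'   normal-tissue program; its structured part is an `effect_size` shift
#'   on the normal-characteristic sets, so benign tissue carries a program
#'   as strong as the tumor subtype programs.
#' @param good_overlap Strength (as a multiple of `effect_size`) of the
#'   normal program on the good-prognosis subtype sets: benign tissue
#'   partially resembles the good-prognosis expression profile, which is
#'   why contamination dilutes bad-prognosis calls.
#' @param frac_normal_range Uniform bounds for the normal-tissue fraction of
#'   cancer samples.
#' @param p_normal_sample Probability that a sample is pure normal tissue
#'   (frac = 1).
#' @param subtype_by `"patient"` (default): all of a patient's samples share
#'   one latent subtype, the within-patient homogeneity the analysis is
#'   meant to detect. `"sample"`: subtypes drawn independently per sample, a
#'   negative control with no patient-level structure once
#'   `patient_effect_sd = 0`.
#' @param seed Integer seed fixing the whole cohort.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_genes = 500L,
                          set_sizes = rep(15L, 15L),
                          overlap_fraction = 0,
                          n_patients = 40L,
                          samples_per_patient = c(3L, 4L),
                          subtype_prevalences = c("BP-E/P/Pr" = 0.40,
                                                  "BP-ERG" = 0.30,
                                                  "GP1" = 0.17,
                                                  "GP2" = 0.13),
                          effect_size = 3,
                          patient_effect_sd = 1.5,
                          noise_sd = 1,
                          normal_profile_sd = 0.5,
                          good_overlap = 0.8,
                          frac_normal_range = c(0, 0.6),
                          p_normal_sample = 0.25,
                          subtype_by = c("patient", "sample"),
                          seed = 1L) {
  subtype_by <- match.arg(subtype_by)
  stopifnot(n_genes >= 10L, all(set_sizes >= 1L),
            overlap_fraction >= 0, overlap_fraction < 1,
            n_patients >= 1L, length(samples_per_patient) == 2L,
            samples_per_patient[1L] >= 1L,
            samples_per_patient[2L] >= samples_per_patient[1L],
            effect_size >= 0, patient_effect_sd >= 0, noise_sd >= 0,
            normal_profile_sd >= 0, good_overlap >= 0,
            length(frac_normal_range) == 2L,
            frac_normal_range[1L] >= 0, frac_normal_range[2L] <= 1,
            frac_normal_range[1L] <= frac_normal_range[2L],
            p_normal_sample >= 0, p_normal_sample < 1)
  if (is.null(names(subtype_prevalences)) ||
      !setequal(names(subtype_prevalences), PROSIG_SUBTYPES))
    stop("subtype_prevalences must be named by the four subtypes")
  if (abs(sum(subtype_prevalences) - 1) > 1e-8)
    stop("subtype_prevalences must sum to 1")
  structure(list(n_genes = as.integer(n_genes),
                 set_sizes = as.integer(set_sizes),
                 overlap_fraction = overlap_fraction,
                 n_patients = as.integer(n_patients),
                 samples_per_patient = as.integer(samples_per_patient),
                 subtype_prevalences = subtype_prevalences[PROSIG_SUBTYPES],
                 effect_size = effect_size,
                 patient_effect_sd = patient_effect_sd,
                 noise_sd = noise_sd,
                 normal_profile_sd = normal_profile_sd,
                 good_overlap = good_overlap,
                 frac_normal_range = frac_normal_range,
                 p_normal_sample = p_normal_sample,
                 subtype_by = subtype_by,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Simulate a gene-set collection with subtype assignments
#'
#' Draws gene sets from a universe of `n_genes` synthetic gene identifiers.
#' With `overlap_fraction = 0` the sets are pairwise disjoint; otherwise
#' each set recruits that fraction of its genes from genes already used by
#' earlier sets. Each set is tagged with the subtype whose expression
#' program it characterizes, cycling through [PROSIG_SUBTYPES] so every
#' subtype owns an equal share of the sets.
#'
#' @param n_genes Gene universe size.
#' @param set_sizes Integer vector of set sizes.
#' @param overlap_fraction Fraction of re-used genes per set, in `[0, 1)`.
#' @param seed Optional integer seed (same seed, same collection).
#' @param programs Expression programs the sets characterize, recycled
#'   across sets. The cohort generator appends a `"normal"` program (the
#'   benign-tissue expression signature) to the four tumor subtypes.
#' @return List with `sets` (named list of gene identifier vectors),
#'   `characteristic` (named character vector, set -> program), and
#'   `gene_ids` (the full universe).
#' @export
simulate_gene_set_collection <- function(n_genes, set_sizes,
                                         overlap_fraction = 0, seed = NULL,
                                         programs = PROSIG_SUBTYPES) {
  if (!is.null(seed)) set.seed(seed)
  n_genes <- as.integer(n_genes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  fresh_needed <- sum(ceiling(set_sizes * (1 - overlap_fraction)))
  if (fresh_needed > n_genes)
    stop("set sizes infeasible: ", fresh_needed,
         " non-overlapping genes needed but universe has ", n_genes)
  used <- character(0)
  sets <- vector("list", length(set_sizes))
  for (i in seq_along(set_sizes)) {
    s <- set_sizes[i]
    n_old <- min(floor(overlap_fraction * s), length(used))
    n_new <- s - n_old
    pool <- setdiff(gene_ids, used)
    if (n_new > length(pool)) stop("gene universe exhausted at set ", i)
    new_genes <- sample(pool, n_new)
    old_genes <- if (n_old > 0L) sample(used, n_old) else character(0)
    sets[[i]] <- c(new_genes, old_genes)
    used <- union(used, new_genes)
  }
  names(sets) <- sprintf("set%02d", seq_along(sets))
  characteristic <- setNames(
    rep_len(programs, length(sets)), names(sets))
  list(sets = sets, characteristic = characteristic, gene_ids = gene_ids)
}

#' Simulate an expression cohort with ground truth
#'
#' Generative model, per gene g and sample i:
#'
#'   x[g, i] = (1 - frac_i) * cancer[g, i] + frac_i * normal[g] + noise
#'
#' where `cancer[g, i] = effect_size * 1(g in a characteristic set of the
#' patient's subtype) + patient_effect[g, patient(i)]` and `normal[g]` is a
#' fixed normal-tissue program shared by all samples:
#' `effect_size * 1(g in a normal-characteristic set) + N(0,
#' normal_profile_sd^2)`. Benign tissue thus carries its own coherent
#' gene-set program of the same strength as the tumor programs (one program
#' per fifth of the sets: four subtypes plus normal), which is what makes
#' tissue composition a genuine confounder of subtype assignment. The
#' noise is i.i.d. `N(0, noise_sd^2)`. Pure normal samples (frac = 1) are
#' `normal[g] + noise`. All samples of one patient share the patient's
#' latent subtype and patient effect, reproducing within-patient signature
#' homogeneity. Gleason scores are drawn independently of subtype (6-9).
#'
#' @param params A [cohort_params()] object.
#' @return List of class `cohort_simulation` with `expr` (genes x samples),
#'   `metadata` (data.frame), `truth` (per-sample subtype, per-patient
#'   subtype, set -> subtype map), `sets`, `gene_ids`, `params`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  coll <- simulate_gene_set_collection(params$n_genes, params$set_sizes,
                                       params$overlap_fraction,
                                       programs = c(PROSIG_SUBTYPES,
                                                    "normal"))
  gene_ids <- coll$gene_ids
  n_genes <- params$n_genes

  patient_ids <- sprintf("P%02d", seq_len(params$n_patients))
  patient_subtype <- setNames(
    sample(PROSIG_SUBTYPES, params$n_patients, replace = TRUE,
           prob = params$subtype_prevalences),
    patient_ids)
  patient_effect <- matrix(
    stats::rnorm(n_genes * params$n_patients, 0, params$patient_effect_sd),
    nrow = n_genes, dimnames = list(gene_ids, patient_ids))
  chr <- coll$characteristic
  in_sets <- function(programs) {
    sel <- names(chr)[chr %in% programs]
    as.numeric(gene_ids %in% unlist(coll$sets[sel], use.names = FALSE))
  }
  normal_profile <- params$effect_size * in_sets("normal") +
    params$good_overlap * params$effect_size * in_sets(c("GP1", "GP2")) +
    stats::rnorm(n_genes, 0, params$normal_profile_sd)
  names(normal_profile) <- gene_ids

  # per-subtype indicator of characteristic-set membership
  subtype_shift <- sapply(PROSIG_SUBTYPES, function(st) {
    chr_sets <- names(coll$characteristic)[coll$characteristic == st]
    as.numeric(gene_ids %in% unlist(coll$sets[chr_sets], use.names = FALSE))
  })
  rownames(subtype_shift) <- gene_ids

  rng <- params$samples_per_patient
  n_samp <- rng[1L] +
    sample.int(rng[2L] - rng[1L] + 1L, params$n_patients, replace = TRUE) - 1L
  rows <- list()
  cols <- list()
  sample_subtype <- character(0)
  k <- 0L
  for (pi in seq_len(params$n_patients)) {
    pid <- patient_ids[pi]
    for (si in seq_len(n_samp[pi])) {
      st <- if (params$subtype_by == "patient") patient_subtype[pid]
            else sample(PROSIG_SUBTYPES, 1L,
                        prob = params$subtype_prevalences)
      k <- k + 1L
      sample_subtype[k] <- st
      sid <- sprintf("s%03d", k)
      is_normal <- stats::runif(1) < params$p_normal_sample
      noise <- stats::rnorm(n_genes, 0, params$noise_sd)
      if (is_normal) {
        x <- normal_profile + noise
        rows[[k]] <- data.frame(sample_id = sid, patient_id = pid,
                                sample_type = "normal",
                                gleason = NA_integer_, frac_normal = 1,
                                stringsAsFactors = FALSE)
      } else {
        frac <- stats::runif(1, params$frac_normal_range[1L],
                             params$frac_normal_range[2L])
        cancer <- params$effect_size * subtype_shift[, st] +
          patient_effect[, pid]
        x <- (1 - frac) * cancer + frac * normal_profile + noise
        gl <- sample(6:9, 1L, prob = c(0.35, 0.35, 0.15, 0.15))
        rows[[k]] <- data.frame(sample_id = sid, patient_id = pid,
                                sample_type = "cancer",
                                gleason = gl, frac_normal = frac,
                                stringsAsFactors = FALSE)
      }
      cols[[k]] <- x
    }
  }
  metadata <- do.call(rbind, rows)
  # at least one normal sample is needed for the composition correction
  if (!any(metadata$sample_type == "normal") && params$p_normal_sample > 0) {
    j <- nrow(metadata)
    metadata$sample_type[j] <- "normal"
    metadata$gleason[j] <- NA_integer_
    metadata$frac_normal[j] <- 1
    cols[[j]] <- normal_profile + stats::rnorm(n_genes, 0, params$noise_sd)
  }
  expr <- do.call(cbind, cols)
  dimnames(expr) <- list(gene_ids, metadata$sample_id)

  truth <- list(
    samples = data.frame(
      sample_id = metadata$sample_id,
      patient_id = metadata$patient_id,
      subtype = ifelse(metadata$sample_type == "cancer",
                       sample_subtype, NA_character_),
      prognosis = ifelse(metadata$sample_type == "cancer",
                         ifelse(sample_subtype %in% PROSIG_SUBTYPES[1:2],
                                "bad", "good"),
                         NA_character_),
      frac_normal = metadata$frac_normal,
      stringsAsFactors = FALSE),
    patient_subtype = patient_subtype,
    characteristic = coll$characteristic)

  structure(list(expr = expr, metadata = metadata, truth = truth,
                 sets = coll$sets, gene_ids = gene_ids, params = params),
            class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples (%d cancer, %d normal) from %d patients\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$metadata$sample_type == "cancer"),
              sum(x$metadata$sample_type == "normal"),
              length(unique(x$metadata$patient_id))))
  invisible(x)
}

#' Build a reference subtype matrix from simulation ground truth
#'
#' For each subtype, a noise-free prototype expression profile (the pure
#' subtype shift on its characteristic sets) is scored through the standard
#' signature pipeline (mean-centering across the four prototypes, running
#' sum, per-sample min-max normalization); the prototype's signature becomes
#' the subtype's reference row. This stands in for a reference matrix
#' digitized from published subtype heatmaps when working with synthetic
#' cohorts.
#'
#' @param sim A `cohort_simulation`, or any list with `sets`,
#'   `truth$characteristic` (or `characteristic`), `gene_ids` and `params`.
#' @param variant Walk weight variant (see [walk_weights()]).
#' @param score_type Scoring direction, matching the cohort fit (see
#'   [fit_subtypes()]).
#' @param mapping Optional related-set grouping applied before
#'   normalization (see [reduce_related_sets()]).
#' @return Reference matrix, subtypes x gene sets, values in `[0, 1]`.
#' @export
make_reference_from_truth <- function(sim, variant = "zero_sum_ks",
                                      score_type = c("signed", "total"),
                                      mapping = NULL) {
  score_type <- match.arg(score_type)
  characteristic <- if (!is.null(sim$truth)) sim$truth$characteristic
                    else sim$characteristic
  effect <- sim$params$effect_size
  if (effect <= 0)
    stop("effect_size is 0: prototype signatures are constant")
  proto <- sapply(PROSIG_SUBTYPES, function(st) {
    chr_sets <- names(characteristic)[characteristic == st]
    effect * as.numeric(sim$gene_ids %in%
                          unlist(sim$sets[chr_sets], use.names = FALSE))
  })
  rownames(proto) <- sim$gene_ids
  raw <- compute_raw_scores(proto, sim$sets, variant,
                            signed = score_type == "signed")
  raw <- reduce_related_sets(raw, mapping)
  sig <- normalize_signatures(raw, "per_sample")
  refs <- t(sig)
  validate_reference_matrix(refs)
  refs
}
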