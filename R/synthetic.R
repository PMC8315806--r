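# Synthetic cohort generator with planted ground truth.
#
# The generator emulates the statistical structure of a multi-site psychosis
# spectrum cohort: a clinical battery of correlated symptom items driven by a
# few latent behavioral factors, and parcellated GBC maps whose inter-subject
# variance is dominated by symptom-irrelevant shared components with smaller
# components linearly coupled to the latent symptom factors.

#' Configuration for a synthetic brain-behavior cohort
#'
#' Defaults mirror the study conditions the package targets: 36 clinical
#' items (30 psychosis-symptom plus 6 cognition scores), 718 whole-brain
#' parcels, five latent symptom factors jointly accounting for about half of
#' the item variance, and neural variance dominated by shared,
#' symptom-irrelevant components.
#'
#' @param n_subjects number of subjects.
#' @param n_items number of clinical items (default 36).
#' @param n_parcels number of parcels (default 718).
#' @param n_latent number of latent symptom factors (default 5).
#' @param latent_variance_fractions per-factor proportion of total item
#'   variance; entries in (0,1), sum < 1 (the remainder is item noise).
#'   Default `c(0.20, 0.11, 0.08, 0.07, 0.05)` (five factors, ~51% jointly).
#' @param item_noise_sd standard deviation of item-level Gaussian noise
#'   before per-item standardization. Default `sqrt(1 - sum(fractions))`.
#' @param n_shared_neural_pcs number of symptom-irrelevant shared neural
#'   components (default 3).
#' @param shared_neural_variance_fraction joint fraction of parcel variance
#'   carried by the shared components (default 0.45); split across
#'   components in geometrically decreasing shares.
#' @param coupling_strengths per-factor scalar linking the factor score to
#'   its planted parcel coefficient map (default 0.5 for every factor).
#' @param signal_parcel_sets list (length `n_latent`) of parcel index
#'   vectors carrying the coupling; default: disjoint blocks of
#'   `min(100, floor(n_parcels / n_latent))` parcels per factor.
#' @param parcel_noise_sd standard deviation of parcel-level noise
#'   (default so that non-signal parcel variance is 1).
#' @param subject_offset_sd standard deviation of the per-subject global GBC
#'   offset (default 0.2).
#' @param factor_correlation optional n_latent x n_latent correlation matrix
#'   for oblique latent factors; default identity (orthogonal factors).
#' @param n_sites number of acquisition sites (default 6).
#' @param n_groups number of diagnostic groups (default 3).
#' @param site_item_effects,site_parcel_effects optional n_sites x n_items /
#'   n_sites x n_parcels additive intercept matrices; default zero.
#' @param seed integer master seed; identical seed and config give a
#'   bit-identical cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          n_items = 36L,
                          n_parcels = 718L,
                          n_latent = 5L,
                          latent_variance_fractions = c(0.20, 0.11, 0.08, 0.07, 0.05),
                          item_noise_sd = NULL,
                          n_shared_neural_pcs = 3L,
                          shared_neural_variance_fraction = 0.45,
                          coupling_strengths = NULL,
                          signal_parcel_sets = NULL,
                          parcel_noise_sd = NULL,
                          subject_offset_sd = 0.2,
                          factor_correlation = NULL,
                          n_sites = 6L,
                          n_groups = 3L,
                          site_item_effects = NULL,
                          site_parcel_effects = NULL,
                          seed = 1L) {
  if (length(latent_variance_fractions) != n_latent)
    stop("latent_variance_fractions must have length n_latent", call. = FALSE)
  if (any(latent_variance_fractions <= 0) || any(latent_variance_fractions >= 1) ||
      sum(latent_variance_fractions) >= 1)
    stop("latent_variance_fractions entries must lie in (0,1) and sum to < 1",
         call. = FALSE)
  if (is.null(item_noise_sd))
    item_noise_sd <- sqrt(1 - sum(latent_variance_fractions))
  if (is.null(coupling_strengths)) coupling_strengths <- rep(0.5, n_latent)
  if (length(coupling_strengths) != n_latent)
    stop("coupling_strengths must have length n_latent", call. = FALSE)
  if (is.null(signal_parcel_sets)) {
    block <- min(100L, max(1L, floor(n_parcels / n_latent)))
    signal_parcel_sets <- lapply(seq_len(n_latent), function(f)
      seq.int((f - 1L) * block + 1L, f * block))
  }
  if (length(signal_parcel_sets) != n_latent)
    stop("signal_parcel_sets must have length n_latent", call. = FALSE)
  idx <- unlist(signal_parcel_sets)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_parcels))
    stop("signal_parcel_sets indices must lie in [1, n_parcels]", call. = FALSE)
  if (is.null(parcel_noise_sd))
    parcel_noise_sd <- sqrt(max(1 - shared_neural_variance_fraction, 0.05))
  if (is.null(factor_correlation)) factor_correlation <- diag(n_latent)
  if (!isTRUE(all.equal(dim(factor_correlation), c(n_latent, n_latent))))
    stop("factor_correlation must be n_latent x n_latent", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), n_items = as.integer(n_items),
    n_parcels = as.integer(n_parcels), n_latent = as.integer(n_latent),
    latent_variance_fractions = latent_variance_fractions,
    item_noise_sd = item_noise_sd,
    n_shared_neural_pcs = as.integer(n_shared_neural_pcs),
    shared_neural_variance_fraction = shared_neural_variance_fraction,
    coupling_strengths = coupling_strengths,
    signal_parcel_sets = lapply(signal_parcel_sets, as.integer),
    parcel_noise_sd = parcel_noise_sd,
    subject_offset_sd = subject_offset_sd,
    factor_correlation = factor_correlation,
    n_sites = as.integer(n_sites), n_groups = as.integer(n_groups),
    site_item_effects = site_item_effects,
    site_parcel_effects = site_parcel_effects,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Symptom items are linear combinations of latent factor scores through
#' planted loadings plus Gaussian noise, standardized per item. GBC per
#' subject is a parcel baseline plus a global subject offset, shared
#' symptom-irrelevant components, factor-coupled coefficient maps restricted
#' to the signal parcel sets, and parcel noise. Diagnosis labels are assigned
#' by quantiles of the first factor score (they do not enter the neural
#' generative model); sites stratify subjects and add optional intercepts.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `symptoms`
#'   (class `symptom_matrix`), `gbc` (class `gbc_matrix`) and `truth`
#'   (planted loadings, factor scores, coefficient maps, shared components,
#'   noise scales).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects; p_it <- config$n_items; p_pc <- config$n_parcels
  k <- config$n_latent

  # latent factor scores (sub-stream 1)
  z <- with_seed(sub_seed(config$seed, 1L), {
    z0 <- matrix(stats::rnorm(n * k), n, k)
    if (!isTRUE(all.equal(config$factor_correlation, diag(k))))
      z0 <- z0 %*% chol(config$factor_correlation)
    z0
  })

  # planted item loadings: random orthogonal columns scaled so that factor f
  # carries latent_variance_fractions[f] of total item variance (sub-stream 2)
  lambda <- with_seed(sub_seed(config$seed, 2L), {
    q <- qr.Q(qr(matrix(stats::rnorm(p_it * k), p_it, k)))
    sweep(q, 2, sqrt(p_it * config$latent_variance_fractions), "*")
  })

  # symptom items (sub-stream 3), standardized per item
  items_raw <- z %*% t(lambda) +
    with_seed(sub_seed(config$seed, 3L),
              matrix(stats::rnorm(n * p_it, sd = config$item_noise_sd), n, p_it))

  # shared symptom-irrelevant neural components (sub-stream 4)
  m <- config$n_shared_neural_pcs
  share_w <- 0.6^(seq_len(m) - 1L)
  share_var <- config$shared_neural_variance_fraction * share_w / sum(share_w)
  shared <- with_seed(sub_seed(config$seed, 4L), {
    maps <- matrix(stats::rnorm(m * p_pc), m, p_pc)
    maps <- maps / sqrt(rowMeans(maps^2))  # unit mean-square per map
    scores <- matrix(stats::rnorm(n * m), n, m)
    list(maps = maps, scores = scores, sds = sqrt(share_var))
  })

  # planted coefficient maps on the signal parcel sets (sub-stream 5)
  coef_maps <- with_seed(sub_seed(config$seed, 5L), {
    cm <- matrix(0, k, p_pc)
    for (f in seq_len(k)) {
      set <- config$signal_parcel_sets[[f]]
      cm[f, set] <- config$coupling_strengths[f] * stats::rnorm(length(set))
    }
    cm
  })

  # assemble GBC (sub-stream 6: baseline, offsets, noise)
  gbc_vals <- with_seed(sub_seed(config$seed, 6L), {
    baseline <- stats::rnorm(p_pc, mean = 0.15, sd = 0.05)
    offset <- stats::rnorm(n, sd = config$subject_offset_sd)
    noise <- matrix(stats::rnorm(n * p_pc, sd = config$parcel_noise_sd), n, p_pc)
    vals <- matrix(baseline, n, p_pc, byrow = TRUE) + offset +
      shared$scores %*% (shared$sds * shared$maps) + z %*% coef_maps + noise
    attr(vals, "baseline") <- baseline
    attr(vals, "offset") <- offset
    vals
  })
  baseline <- attr(gbc_vals, "baseline"); offset <- attr(gbc_vals, "offset")
  attr(gbc_vals, "baseline") <- NULL; attr(gbc_vals, "offset") <- NULL

  # site and diagnosis labels (sub-stream 7); diagnosis by factor-1 quantiles
  labels <- with_seed(sub_seed(config$seed, 7L), {
    site <- sample(rep_len(seq_len(config$n_sites), n))
    br <- stats::quantile(z[, 1], probs = seq(0, 1, length.out = config$n_groups + 1L))
    diagnosis <- cut(z[, 1], breaks = br, labels = FALSE, include.lowest = TRUE)
    list(site = paste0("site", site),
         diagnosis = paste0("G", diagnosis))
  })

  if (!is.null(config$site_item_effects))
    items_raw <- items_raw + config$site_item_effects[match(labels$site,
      paste0("site", seq_len(config$n_sites))), , drop = FALSE]
  if (!is.null(config$site_parcel_effects))
    gbc_vals <- gbc_vals + config$site_parcel_effects[match(labels$site,
      paste0("site", seq_len(config$n_sites))), , drop = FALSE]

  item_sc <- standardize_columns(items_raw)
  subject_ids <- sprintf("S%04d", seq_len(n))
  item_ids <- sprintf("item%02d", seq_len(p_it))
  parcel_ids <- sprintf("parcel%03d", seq_len(p_pc))

  symptoms <- symptom_matrix(item_sc$values, item_ids = item_ids,
                             subject_ids = subject_ids,
                             diagnosis = labels$diagnosis, site = labels$site)
  gbc <- gbc_matrix(gbc_vals, parcel_ids = parcel_ids,
                    subject_ids = subject_ids,
                    diagnosis = labels$diagnosis, site = labels$site)

  truth <- list(
    loadings = lambda,
    loadings_std = lambda / item_sc$scale,  # in standardized-item space
    factor_scores = z, coef_maps = coef_maps,
    shared_maps = shared$maps, shared_scores = shared$scores,
    shared_sds = shared$sds, baseline = baseline, subject_offset = offset,
    item_scaling = list(center = item_sc$center, scale = item_sc$scale),
    item_noise_sd = config$item_noise_sd,
    parcel_noise_sd = config$parcel_noise_sd,
    subject_offset_sd = config$subject_offset_sd,
    signal_parcel_sets = config$signal_parcel_sets,
    coupling_strengths = config$coupling_strengths)

  structure(list(symptoms = symptoms, gbc = gbc, truth = truth,
                 config = config), class = "synthetic_cohort")
}

#' Construct a symptom matrix container
#'
#' @param values subjects x items numeric matrix (no missing values).
#' @param item_ids,subject_ids axis labels.
#' @param diagnosis,site per-subject labels.
#' @export
symptom_matrix <- function(values, item_ids = colnames(values),
                           subject_ids = rownames(values),
                           diagnosis = NULL, site = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("symptom matrix must not contain missing values",
                          call. = FALSE)
  if (is.null(item_ids)) item_ids <- sprintf("item%02d", seq_len(ncol(values)))
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(nrow(values)))
  dimnames(values) <- list(subject_ids, item_ids)
  structure(list(values = values, item_ids = item_ids,
                 subject_ids = subject_ids, diagnosis = diagnosis,
                 site = site), class = "symptom_matrix")
}

#' Construct a GBC matrix container
#'
#' @param values subjects x parcels numeric matrix (Fisher-z units).
#' @param parcel_ids,subject_ids axis labels.
#' @param diagnosis,site per-subject labels.
#' @export
gbc_matrix <- function(values, parcel_ids = colnames(values),
                       subject_ids = rownames(values),
                       diagnosis = NULL, site = NULL) {
  values <- as.matrix(values)
  assert_finite(values, "GBC matrix")
  if (is.null(parcel_ids)) parcel_ids <- sprintf("parcel%03d", seq_len(ncol(values)))
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(nrow(values)))
  dimnames(values) <- list(subject_ids, parcel_ids)
  structure(list(values = values, parcel_ids = parcel_ids,
                 subject_ids = subject_ids, diagnosis = diagnosis,
                 site = site), class = "gbc_matrix")
}

# Extract the numeric matrix from a container or plain matrix.
#' @noRd
mat_values <- function(x) {
  if (inherits(x, c("symptom_matrix", "gbc_matrix"))) x$values else as.matrix(x)
}

#' Generate a reference map with a prescribed similarity to a source map
#'
#' Builds a parcel vector whose Pearson correlation with `truth_map` equals
#' `target_similarity` by mixing the standardized source with a random
#' orthogonal residual: `v = s * t_hat + sqrt(1 - s^2) * g_hat`.
#'
#' @param truth_map non-constant numeric parcel vector.
#' @param target_similarity correlation in [-1, 1].
#' @param seed integer seed for the residual draw.
#' @return numeric vector of the same length as `truth_map`.
#' @export
generate_reference_map <- function(truth_map, target_similarity, seed = 1L) {
  if (abs(target_similarity) > 1)
    stop("target_similarity must lie in [-1, 1]", call. = FALSE)
  t <- as.numeric(truth_map)
  if (stats::sd(t) == 0) stop("truth_map must be non-constant", call. = FALSE)
  tc <- t - mean(t)
  that <- tc / sqrt(sum(tc^2))
  if (abs(target_similarity) == 1) return(target_similarity * t)
  g <- with_seed(seed, stats::rnorm(length(t)))
  g <- g - mean(g)
  g <- g - sum(g * that) * that
  ghat <- g / sqrt(sum(g^2))
  target_similarity * that + sqrt(1 - target_similarity^2) * ghat
}

#' Write a synthetic cohort to tab-delimited text
#'
#' Writes `symptoms.tsv`, `gbc.tsv`, `labels.tsv` and the planted truth
#' (`truth_loadings.tsv`, `truth_coef_maps.tsv`, `truth_factor_scores.tsv`)
#' into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$symptoms$values, file.path(dir, "symptoms.tsv"))
  write_matrix(cohort$gbc$values, file.path(dir, "gbc.tsv"))
  lab <- data.frame(subject_id = cohort$symptoms$subject_ids,
                    diagnosis = cohort$symptoms$diagnosis,
                    site = cohort$symptoms$site)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(cohort$truth$loadings, file.path(dir, "truth_loadings.tsv"))
  write_matrix(cohort$truth$coef_maps, file.path(dir, "truth_coef_maps.tsv"))
  write_matrix(cohort$truth$factor_scores,
               file.path(dir, "truth_factor_scores.tsv"))
  invisible(dir)
}
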