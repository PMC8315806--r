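# Spatial similarity of coefficient / selected maps to reference maps
# (pharmacological contrasts, gene-expression patterns) and two-stage
# single-patient selection.

#' Spatial similarity between two parcel maps
#'
#' Rank (Spearman, default) or linear (Pearson) correlation over an
#' optional parcel subset. Maps in different parcel spaces must be
#' symmetrized explicitly first; no implicit resampling is performed.
#'
#' @param a,b numeric parcel vectors of equal length.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param subset optional parcel indices.
#' @return correlation in [-1, 1].
#' @export
map_similarity <- function(a, b, method = c("spearman", "pearson"),
                           subset = NULL) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("maps differ in length", call. = FALSE)
  if (!is.null(subset)) { a <- a[subset]; b <- b[subset] }
  if (length(a) < 3L) stop("need at least 3 parcels", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant map", call. = FALSE)
  stats::cor(a, b, method = method)
}

#' Pharmacological contrast reference map
#'
#' Per-parcel paired (or unpaired Welch) t statistic between drug and
#' placebo GBC, Z-scored across parcels.
#'
#' @param gbc_drug,gbc_placebo [gbc_matrix()] or subjects x parcels
#'   matrices; matched subject order required when `paired = TRUE`.
#' @param paired paired t-test (default TRUE).
#' @param label map label stored with the result.
#' @return list of class `reference_map`: `values` (Z-scored t map),
#'   `tvalues`, `label`.
#' @export
pharma_contrast <- function(gbc_drug, gbc_placebo, paired = TRUE,
                            label = "drug-placebo") {
  d <- mat_values(gbc_drug); p <- mat_values(gbc_placebo)
  if (ncol(d) != ncol(p)) stop("parcel counts differ", call. = FALSE)
  if (paired && nrow(d) != nrow(p))
    stop("paired contrast requires matched subjects", call. = FALSE)
  tval <- if (paired) {
    diff <- d - p
    m <- colMeans(diff); sdd <- apply(diff, 2, stats::sd)
    ifelse(sdd > 0, m / (sdd / sqrt(nrow(diff))), 0)
  } else {
    vapply(seq_len(ncol(d)), function(j)
      stats::t.test(d[, j], p[, j])$statistic, numeric(1))
  }
  z <- if (stats::sd(tval) > 0) (tval - mean(tval)) / stats::sd(tval)
       else tval
  pid <- colnames(d)
  if (is.null(pid)) pid <- sprintf("parcel%03d", seq_along(z))
  structure(list(values = stats::setNames(z, pid),
                 tvalues = stats::setNames(tval, pid), label = label),
            class = "reference_map")
}

#' Two-stage symptom-then-neural patient selection
#'
#' Stage 1 keeps subjects whose absolute component score reaches
#' `symptom_threshold` (the symptom axes are bi-directional: both extremes
#' are symptomatic). Stage 2 keeps those whose deviation-map similarity to
#' the reference coefficient map has magnitude at least `neural_threshold`
#' and sign consistent with the sign of their score.
#'
#' @param scores subject score vector on the chosen symptom component.
#' @param delta subjects x parcels deviation matrix (see [delta_gbc()]).
#' @param beta_map parcel vector reference coefficient map.
#' @param symptom_threshold nonnegative score cutoff; default the 75th
#'   percentile of |score|.
#' @param neural_threshold nonnegative similarity cutoff (default 0.25).
#' @param subset optional parcel indices for the similarity.
#' @param method correlation method for the similarity (default spearman).
#' @return data.frame with `subject`, `score`, `similarity` for selected
#'   subjects.
#' @export
select_patients <- function(scores, delta, beta_map,
                            symptom_threshold = NULL,
                            neural_threshold = 0.25, subset = NULL,
                            method = "spearman") {
  s <- as.numeric(scores)
  d <- as.matrix(delta)
  if (is.null(symptom_threshold))
    symptom_threshold <- stats::quantile(abs(s), 0.75)
  if (symptom_threshold < 0 || neural_threshold < 0)
    stop("thresholds must be nonnegative", call. = FALSE)
  if (!is.null(subset) && !length(subset))
    stop("subset must be nonempty", call. = FALSE)
  bm <- if (inherits(beta_map, "beta_map")) beta_map$coefficients
        else as.numeric(beta_map)
  stage1 <- which(abs(s) >= symptom_threshold)
  sim <- vapply(stage1, function(i)
    map_similarity(d[i, ], bm, method = method, subset = subset),
    numeric(1))
  keep <- abs(sim) >= neural_threshold & sign(sim) == sign(s[stage1]) &
    sign(s[stage1]) != 0
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  data.frame(subject = ids[stage1[keep]], score = s[stage1[keep]],
             similarity = sim[keep], row.names = NULL)
}

#' Rank a map against a set of reference vectors
#'
#' Correlates one coefficient map against every column of a reference-map
#' matrix (e.g. a panel of gene-expression patterns) and returns the
#' ranked distribution of similarities.
#'
#' @param map parcel vector.
#' @param references parcels x maps matrix (columns are reference vectors).
#' @param method correlation method (default spearman).
#' @return data.frame sorted by decreasing similarity.
#' @export
benchmark_against_references <- function(map, references,
                                         method = "spearman") {
  refs <- as.matrix(references)
  if (nrow(refs) != length(map))
    stop("reference maps must share the map's parcel space", call. = FALSE)
  sims <- vapply(seq_len(ncol(refs)), function(j)
    map_similarity(map, refs[, j], method = method), numeric(1))
  labs <- colnames(refs)
  if (is.null(labs)) labs <- sprintf("ref%03d", seq_len(ncol(refs)))
  out <- data.frame(reference = labs, similarity = sims)
  out[order(-out$similarity), , drop = FALSE]
}
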