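# Frame scrubbing and parcel-level global brain connectivity (GBC).

#' Frame-censoring keep-mask from motion statistics
#'
#' A frame is flagged when its frame displacement (sum of displacement over
#' the six rigid-body parameters, mm) exceeds `fd_threshold`, or when its
#' normalized intensity RMS change exceeds `rms_multiplier` times the median
#' RMS across the scan. Flagged frames plus the frame immediately preceding
#' and immediately following are discarded. Neighbor removal is single-pass:
#' a frame removed only as a neighbor does not itself spawn removals.
#'
#' @param frame_displacement per-frame displacement in mm.
#' @param intensity_rms per-frame normalized RMS signal change.
#' @param fd_threshold displacement threshold in mm (default 0.5).
#' @param rms_multiplier multiplier of the median RMS (default 1.6).
#' @return logical keep-mask (TRUE = retain frame).
#' @export
scrub_mask <- function(frame_displacement, intensity_rms,
                       fd_threshold = 0.5, rms_multiplier = 1.6) {
  fd <- as.numeric(frame_displacement); rms <- as.numeric(intensity_rms)
  if (length(fd) == 0L || length(fd) != length(rms))
    stop("frame statistics must be non-empty vectors of equal length",
         call. = FALSE)
  if (any(fd < 0) || any(rms < 0))
    stop("frame statistics must be non-negative", call. = FALSE)
  if (fd_threshold <= 0 || rms_multiplier <= 0)
    stop("thresholds must be positive", call. = FALSE)
  flagged <- fd > fd_threshold | rms > rms_multiplier * stats::median(rms)
  drop <- flagged
  drop[which(flagged) - 1L] <- TRUE
  after <- which(flagged) + 1L
  drop[after[after <= length(fd)]] <- TRUE
  !drop
}

#' Fraction of frames flagged for a subject
#'
#' Subjects with more than `max_fraction` frames flagged should be excluded
#' from analysis.
#'
#' @inheritParams scrub_mask
#' @param max_fraction exclusion threshold (default 0.5).
#' @return list with `flagged_fraction` and logical `exclude`.
#' @export
scrub_exclusion <- function(frame_displacement, intensity_rms,
                            fd_threshold = 0.5, rms_multiplier = 1.6,
                            max_fraction = 0.5) {
  keep <- scrub_mask(frame_displacement, intensity_rms, fd_threshold,
                     rms_multiplier)
  frac <- mean(!keep)
  list(flagged_fraction = frac, exclude = frac > max_fraction)
}

#' Average dense time series into parcels
#'
#' Parcel series are the unweighted mean of member-vertex series; the
#' parcellate-before-GBC ordering increases within-parcel signal-to-noise
#' and yields stronger group statistics than parcellating GBC maps.
#'
#' @param dense_series vertices x timepoints numeric matrix.
#' @param parcel_assignment per-vertex parcel id (any label type).
#' @param parcel_ids optional parcel order; default sorted unique labels.
#' @return parcels x timepoints matrix with parcel ids as row names.
#' @export
parcellate <- function(dense_series, parcel_assignment, parcel_ids = NULL) {
  dense_series <- as.matrix(dense_series)
  if (length(parcel_assignment) != nrow(dense_series))
    stop("parcel_assignment must have one entry per vertex", call. = FALSE)
  if (is.null(parcel_ids)) parcel_ids <- sort(unique(parcel_assignment))
  missing_p <- setdiff(parcel_ids, unique(parcel_assignment))
  if (length(missing_p))
    stop("parcel(s) with zero vertices: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  out <- t(vapply(parcel_ids, function(p) {
    rows <- which(parcel_assignment == p)
    colMeans(dense_series[rows, , drop = FALSE])
  }, numeric(ncol(dense_series))))
  rownames(out) <- as.character(parcel_ids)
  out
}

#' Apply a frame keep-mask to a time-series matrix
#'
#' Censored frames are deleted (column removal), not interpolated.
#'
#' @param series parcels (or vertices) x timepoints matrix.
#' @param keep_mask logical vector, one entry per timepoint.
#' @return the censored matrix.
#' @export
apply_scrub <- function(series, keep_mask) {
  series <- as.matrix(series)
  if (length(keep_mask) != ncol(series))
    stop("keep_mask length must equal the number of timepoints", call. = FALSE)
  out <- series[, keep_mask, drop = FALSE]
  if (ncol(out) < 2L)
    stop("fewer than 2 timepoints retained after scrubbing", call. = FALSE)
  out
}

#' Residualize parcel series on a nuisance regressor matrix
#'
#' Ordinary least-squares removal of supplied nuisance signals (e.g.
#' ventricle, white-matter and global means plus first derivatives) from
#' every parcel series. An intercept is always included.
#'
#' @param series parcels x timepoints matrix.
#' @param regressors timepoints x k matrix of nuisance signals.
#' @return residualized series of the same dimensions.
#' @export
regress_nuisance <- function(series, regressors) {
  series <- as.matrix(series); regressors <- as.matrix(regressors)
  if (nrow(regressors) != ncol(series))
    stop("regressors must have one row per timepoint", call. = FALSE)
  x <- cbind(1, regressors)
  fit <- stats::lm.fit(x, t(series))
  t(fit$residuals)
}

#' Parcel-level global brain connectivity
#'
#' For each parcel p, GBC(p) is the mean Fisher r-to-z transformed Pearson
#' correlation of its time series with every other parcel's series. The
#' self-correlation (r = 1, infinite z) is excluded from the average, which
#' is the only finite reading of the row-mean of the FC matrix.
#'
#' @param series parcels x timepoints matrix (>= 3 timepoints; every parcel
#'   must have nonzero temporal variance).
#' @return named numeric vector of GBC values (Fisher-z units), one per
#'   parcel.
#' @export
compute_gbc <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  v <- apply(series, 1, stats::sd)
  if (any(v == 0)) {
    nm <- rownames(series)[v == 0]
    if (is.null(nm)) nm <- as.character(which(v == 0))
    stop("zero-variance parcel(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(t(series))
  # clamp numerically-perfect off-diagonal correlations away from |r| = 1
  r[r > 1 - 1e-15] <- 1 - 1e-15
  r[r < -1 + 1e-15] <- -1 + 1e-15
  z <- atanh(r)
  diag(z) <- 0
  out <- rowSums(z) / (nrow(series) - 1L)
  names(out) <- rownames(series)
  out
}

#' GBC matrix for a list of subjects' parcel time series
#'
#' @param series_list list of parcels x timepoints matrices, one per
#'   subject, with identical parcel order.
#' @param subject_ids optional subject labels.
#' @return a [gbc_matrix()].
#' @export
gbc_from_series <- function(series_list, subject_ids = names(series_list)) {
  vals <- t(vapply(series_list, compute_gbc,
                   numeric(nrow(series_list[[1]]))))
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_along(series_list))
  gbc_matrix(vals, parcel_ids = rownames(series_list[[1]]),
             subject_ids = subject_ids)
}

#' Average homologous left/right cortical parcels
#'
#' Collapses a 2P-parcel cortical vector to P symmetrized parcels by
#' averaging each (left, right) homologue pair.
#'
#' @param map numeric vector over cortical parcels (length 2P), or a
#'   subjects x 2P matrix.
#' @param homologue_pairs two-column integer matrix of (left, right)
#'   indices forming a perfect matching of the parcels.
#' @return vector of length P (or subjects x P matrix), one value per pair,
#'   in pair order.
#' @export
symmetrize_cortex <- function(map, homologue_pairs) {
  hp <- as.matrix(homologue_pairs)
  if (ncol(hp) != 2L) stop("homologue_pairs must have two columns", call. = FALSE)
  n_parcel <- if (is.matrix(map)) ncol(map) else length(map)
  idx <- sort(as.integer(hp))
  if (!identical(idx, seq_len(n_parcel)))
    stop("homologue_pairs must form a perfect matching of all parcels",
         call. = FALSE)
  if (is.matrix(map)) {
    (map[, hp[, 1], drop = FALSE] + map[, hp[, 2], drop = FALSE]) / 2
  } else {
    (map[hp[, 1]] + map[hp[, 2]]) / 2
  }
}
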