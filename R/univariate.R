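# Mass-univariate symptom-neural mapping: per-parcel OLS of GBC on a
# symptom score, Z-scored coefficient maps, max-statistic permutation
# family-wise error control, and shared neural-variance partialling.

#' Map a symptom score onto parcel GBC by mass-univariate regression
#'
#' Per parcel, the ordinary least-squares slope of GBC on the score
#' (intercept included). Coefficients are Z-scored across parcels so that
#' maps are comparable across predictors. An optional covariate matrix is
#' residualized out of both sides first.
#'
#' @param scores numeric subject vector (the predictor).
#' @param gbc a [gbc_matrix()] or subjects x parcels matrix.
#' @param covariates optional subjects x c matrix residualized from scores
#'   and GBC before fitting.
#' @param predictor_id label stored with the map.
#' @return object of class `beta_map`: `coefficients`, `zscores`,
#'   `tvalues`, `parcel_ids`, `predictor_id`.
#' @export
map_symptom_to_gbc <- function(scores, gbc, covariates = NULL,
                               predictor_id = "score") {
  g <- mat_values(gbc)
  s <- as.numeric(scores)
  if (length(s) != nrow(g))
    stop("scores length must equal the number of subjects", call. = FALSE)
  if (!all(is.finite(s)) || !all(is.finite(g)))
    stop("scores and GBC must be finite", call. = FALSE)
  if (stats::sd(s) == 0)
    stop("degenerate predictor: score vector is constant", call. = FALSE)
  if (!is.null(covariates)) {
    cv <- cbind(1, as.matrix(covariates))
    s <- stats::lm.fit(cv, s)$residuals
    g <- stats::lm.fit(cv, g)$residuals
    if (stats::sd(s) == 0)
      stop("degenerate predictor after covariate residualization",
           call. = FALSE)
  }
  n <- length(s)
  sc <- s - mean(s)
  gc <- sweep(g, 2, colMeans(g), "-")
  sxx <- sum(sc^2)
  beta <- as.numeric(crossprod(gc, sc)) / sxx
  # residual variance and t statistic per parcel
  rss <- colSums(gc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / pmax(n - 2L, 1L) / sxx)
  tval <- ifelse(se > 0, beta / se, 0)
  bsd <- stats::sd(beta)
  if (bsd == 0)
    stop("coefficient map is constant; cannot Z-score", call. = FALSE)
  z <- (beta - mean(beta)) / bsd
  pid <- colnames(g)
  if (is.null(pid)) pid <- sprintf("parcel%03d", seq_along(beta))
  structure(list(coefficients = stats::setNames(beta, pid),
                 zscores = stats::setNames(z, pid),
                 tvalues = stats::setNames(tval, pid),
                 parcel_ids = pid, predictor_id = predictor_id,
                 n = n), class = "beta_map")
}

#' Max-statistic permutation family-wise error control
#'
#' Shuffles the predictor across subjects, recomputes every parcel's |t|
#' statistic per permutation and records the maximum; the corrected p-value
#' of a parcel is the add-one permutation tail probability of the max-null
#' at its observed |t|. Controls the family-wise error rate strongly at the
#' parcel level while preserving the spatial covariance of GBC.
#'
#' @inheritParams map_symptom_to_gbc
#' @param n_perm number of permutations (>= 500).
#' @param seed integer seed.
#' @return list with `p_fwe` (per-parcel corrected p-values), the observed
#'   `beta_map`, and `max_null` (the permutation max-|t| distribution).
#' @export
permutation_fwe <- function(scores, gbc, n_perm = 2000L, seed = 1L) {
  if (n_perm < 500L) stop("n_perm must be at least 500", call. = FALSE)
  g <- mat_values(gbc)
  s <- as.numeric(scores)
  bm <- map_symptom_to_gbc(s, g)
  n <- length(s)
  # |t| is a monotone transform of |r|; work with correlations, vectorized
  # over permutations in one cross-product
  gs <- scale(g)
  perm <- with_seed(seed, replicate(n_perm, sample(s)))
  ps <- scale(perm)
  rmat <- crossprod(gs, ps) / (n - 1L)  # parcels x n_perm
  max_r <- apply(abs(rmat), 2, max)
  max_null <- max_r * sqrt(n - 2L) / sqrt(pmax(1 - max_r^2, 1e-12))
  obs_t <- abs(bm$tvalues)
  p_fwe <- vapply(obs_t, function(t0) perm_pvalue(max_null, t0), numeric(1))
  list(p_fwe = stats::setNames(p_fwe, bm$parcel_ids), beta_map = bm,
       max_null = max_null, n_perm = n_perm)
}

#' Principal components of parcellated GBC
#'
#' Same unit-variance PCA algebra as the symptom PCA, applied to a subjects
#' x parcels GBC matrix (typically patients and controls combined, so that
#' the leading components capture neural variance shared across groups).
#' With n subjects and p > n parcels there are at most n - 1 nonzero
#' components. Permutation significance for this solution should shuffle
#' parcels within subject (`permutation_significance(..., shuffle =
#' "within_rows")`).
#'
#' @param gbc a [gbc_matrix()] or subjects x parcels matrix.
#' @return a `pca_solution` over parcels.
#' @export
fit_neural_pca <- function(gbc) {
  fit_pca(mat_values(gbc))
}

#' Reconstruct GBC with leading shared components removed
#'
#' Projects patient GBC into a neural PCA solution (typically fitted on
#' patients plus controls) and reconstructs it from all components except
#' the first `drop_k`, re-adding per-parcel means and scales. The removed
#' variance is exactly the span of the dropped components: the residual
#' (input minus reconstruction) is orthogonal to the retained ones.
#'
#' @param gbc_patients a [gbc_matrix()] or matrix to reconstruct.
#' @param neural_solution a `pca_solution` from [fit_neural_pca()].
#' @param drop_k number of leading components to remove (0 <= drop_k <
#'   number of components).
#' @return reconstructed subjects x parcels matrix.
#' @export
partial_out_neural_pcs <- function(gbc_patients, neural_solution, drop_k) {
  stopifnot(inherits(neural_solution, "pca_solution"))
  x <- mat_values(gbc_patients)
  L <- neural_solution$loadings
  if (drop_k < 0L || drop_k > ncol(L))
    stop("drop_k must lie in [0, ", ncol(L), "]", call. = FALSE)
  xs <- standardize_columns(x, center = neural_solution$scaling$center,
                            scale = neural_solution$scaling$scale)$values
  if (drop_k > 0L) {
    Ld <- L[, seq_len(drop_k), drop = FALSE]
    xs <- xs - (xs %*% Ld) %*% t(Ld)
  }
  sweep(sweep(xs, 2, neural_solution$scaling$scale, "*"), 2,
        neural_solution$scaling$center, "+")
}
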