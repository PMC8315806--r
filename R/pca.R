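# Unit-variance symptom PCA with permutation significance and held-out
# score projection.

#' Principal component analysis of a clinical symptom battery
#'
#' Items are scaled to unit variance across subjects and the PCA is the
#' eigen-decomposition of the item correlation matrix. Loadings carry a
#' deterministic sign convention (the largest-magnitude element of every
#' column is positive) so that solutions are comparable across resamples.
#' The per-item means and standard deviations are stored for projecting
#' held-out subjects.
#'
#' @param data a [symptom_matrix()] or plain subjects x items matrix with no
#'   missing values and nonzero variance for every item.
#' @return object of class `pca_solution`: `loadings` (items x components),
#'   `scores` (subjects x components), `eigenvalues`, `variance_fraction`,
#'   `scaling` (per-item center/scale), `item_ids`.
#' @export
fit_pca <- function(data) {
  x <- mat_values(data)
  if (anyNA(x)) stop("missing values are rejected, not imputed", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("item%02d", seq_len(ncol(x)))
  sc <- standardize_columns(x)
  cmat <- stats::cor(x)
  es <- eigen(cmat, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  loadings <- fix_column_signs(es$vectors)$values
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  rownames(loadings) <- colnames(sc$values)
  scores <- sc$values %*% loadings
  structure(list(loadings = loadings, scores = scores, eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 scaling = list(center = sc$center, scale = sc$scale),
                 item_ids = colnames(sc$values)),
            class = "pca_solution")
}

#' Permutation significance of principal components
#'
#' Builds the null distribution of each component's variance fraction by
#' independently shuffling subject order within every item and re-computing
#' the PCA. Component k is compared against the rank-k null (the Horn-style
#' reading of variance "exceeding chance"); p-values use the add-one
#' estimator and can therefore never be exactly zero.
#'
#' @inheritParams fit_pca
#' @param n_perm number of permutations (>= 100; 5000 for final inference).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @param shuffle `"columns"` (default; shuffle subjects independently per
#'   item) or `"within_rows"` (shuffle features within each subject, used
#'   for the neural GBC-PCA variant).
#' @return list with `pvalues`, `significant` (logical), `n_significant`,
#'   `observed` variance fractions, and the fitted `solution`.
#' @export
permutation_significance <- function(data, n_perm = 1000L, alpha = 0.05,
                                     seed = 1L,
                                     shuffle = c("columns", "within_rows")) {
  shuffle <- match.arg(shuffle)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  x <- mat_values(data)
  sol <- fit_pca(x)
  n <- nrow(x); p <- ncol(x)
  obs <- sol$variance_fraction
  null_vf <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      xp <- if (shuffle == "columns") {
        apply(x, 2, sample)
      } else {
        t(apply(x, 1, sample))
      }
      ev <- eigen(stats::cor(xp), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      ev / sum(ev)
    }, numeric(p))
  })
  pvals <- vapply(seq_len(p), function(k) perm_pvalue(null_vf[k, ], obs[k]),
                  numeric(1))
  sig <- pvals < alpha
  list(pvalues = pvals, significant = sig, n_significant = sum(sig),
       observed = obs, solution = sol, n_perm = n_perm, alpha = alpha)
}

#' Project new subjects into an existing PCA solution
#'
#' Held-out subjects' raw scores are standardized with the training means
#' and standard deviations and weighted by the training loadings. Training
#' data projected through its own solution reproduces the stored scores.
#'
#' @param solution a `pca_solution`.
#' @param new_data a [symptom_matrix()] or matrix whose items match the
#'   solution's `item_ids`.
#' @return subjects x components score matrix.
#' @export
project_scores <- function(solution, new_data) {
  stopifnot(inherits(solution, "pca_solution"))
  x <- mat_values(new_data)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(solution$item_ids))
    stop("item mismatch: expected ", length(solution$item_ids), " items",
         call. = FALSE)
  if (!is.null(colnames(x)) && !identical(colnames(x), solution$item_ids))
    stop("item mismatch: column names differ from the solution's item_ids",
         call. = FALSE)
  xs <- standardize_columns(x, center = solution$scaling$center,
                            scale = solution$scaling$scale)$values
  xs %*% solution$loadings
}

#' Leave-one-out predicted component scores
#'
#' For each subject, fits the PCA on the remaining subjects and projects the
#' held-out subject; components are matched to the full-sample solution by
#' greedy absolute correlation and sign-aligned.
#'
#' @inheritParams fit_pca
#' @param n_components number of leading components to evaluate.
#' @return list with `predicted` (subjects x components), `observed`
#'   (full-sample scores), and `correlation` per component.
#' @export
loo_projected_scores <- function(data, n_components = 5L) {
  x <- mat_values(data)
  n <- nrow(x)
  full <- fit_pca(x)
  k <- min(n_components, ncol(full$loadings))
  pred <- matrix(NA_real_, n, k)
  full_l <- full$loadings[, seq_len(k), drop = FALSE]
  for (i in seq_len(n)) {
    sol_i <- fit_pca(x[-i, , drop = FALSE])
    # align this fit's components with the full-sample solution by loading
    # similarity (guards against order swaps of close eigenvalues)
    mm <- match_components(full_l, sol_i$loadings)
    p_all <- project_scores(sol_i, x[i, , drop = FALSE])
    pred[i, ] <- p_all[1, mm$b] * sign(mm$r)
  }
  observed <- full$scores[, seq_len(k), drop = FALSE]
  list(predicted = pred, observed = observed,
       correlation = vapply(seq_len(k), function(j)
         stats::cor(pred[, j], observed[, j]), numeric(1)))
}
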