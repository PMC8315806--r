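# Canonical correlation analysis between neural and symptom feature sets:
# fitting via the whitened cross-covariance SVD, permutation mode
# significance with FDR, variance-explained decomposition, loading
# projection, leave-one-subject-out latent prediction, and the generative
# power analysis for required sample size.

# Internal: whitening matrix Sigma^{-1/2} from a covariance matrix.
#' @noRd
inv_sqrt <- function(s, tol = 1e-10) {
  es <- eigen(s, symmetric = TRUE)
  if (min(es$values) < tol * max(es$values))
    stop("rank-deficient feature set; reduce the number of features ",
         "(e.g. parcel symmetrization or a PCA first)", call. = FALSE)
  es$vectors %*% (t(es$vectors) / sqrt(es$values))
}

#' Canonical correlation analysis of two feature sets
#'
#' Features are Z-scored per column; the solution is the singular value
#' decomposition of the whitened cross-covariance, giving min(p, q)
#' canonical modes with non-increasing canonical correlations and
#' unit-variance, mutually uncorrelated latent variates. The sign of each
#' mode is fixed so that the largest-magnitude element of the symptom-side
#' weight vector is positive.
#'
#' @param neural subjects x p matrix (neural features, e.g. symmetrized
#'   cortical GBC).
#' @param symptoms subjects x q matrix (symptom features, e.g. PC scores).
#' @return object of class `cca_solution`: `psi` (symptom-side weights,
#'   q x modes), `theta` (neural-side weights, p x modes), `u_scores`
#'   (neural variates U), `v_scores` (symptom variates V),
#'   `canonical_correlations`, structure loadings (`neural_loadings`,
#'   `symptom_loadings`), and the per-set scaling.
#' @export
fit_cca <- function(neural, symptoms) {
  x <- mat_values(neural); y <- mat_values(symptoms)
  if (nrow(x) != nrow(y)) stop("subject counts differ", call. = FALSE)
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (n <= p + q)
    stop("CCA requires more subjects (", n, ") than total features (",
         p + q, "); reduce the feature space", call. = FALSE)
  sx <- standardize_columns(x); sy <- standardize_columns(y)
  xs <- sx$values; ys <- sy$values
  sxx <- crossprod(xs) / (n - 1); syy <- crossprod(ys) / (n - 1)
  sxy <- crossprod(xs, ys) / (n - 1)
  wx <- inv_sqrt(sxx); wy <- inv_sqrt(syy)
  k <- min(p, q)
  sv <- svd(wx %*% sxy %*% wy, nu = k, nv = k)
  theta <- wx %*% sv$u            # p x k neural-side weights
  psi <- wy %*% sv$v              # q x k symptom-side weights
  flip <- fix_column_signs(psi)$flip
  psi <- sweep(psi, 2, flip, "*"); theta <- sweep(theta, 2, flip, "*")
  u <- xs %*% theta; v <- ys %*% psi
  r <- pmin(sv$d[seq_len(k)], 1)
  modes <- paste0("CV", seq_len(k))
  colnames(psi) <- colnames(theta) <- colnames(u) <- colnames(v) <- modes
  rownames(theta) <- colnames(xs); rownames(psi) <- colnames(ys)
  structure(list(
    psi = psi, theta = theta, u_scores = u, v_scores = v,
    canonical_correlations = stats::setNames(r, modes),
    neural_loadings = stats::cor(xs, u),
    symptom_loadings = stats::cor(ys, v),
    scaling = list(neural = list(center = sx$center, scale = sx$scale),
                   symptoms = list(center = sy$center, scale = sy$scale)),
    n = n), class = "cca_solution")
}

#' Project subjects into a fitted CCA solution
#'
#' @param solution a `cca_solution`.
#' @param neural,symptoms matrices of new subjects (either or both).
#' @return list with `u` (from neural) and/or `v` (from symptoms).
#' @export
project_cca <- function(solution, neural = NULL, symptoms = NULL) {
  stopifnot(inherits(solution, "cca_solution"))
  out <- list()
  if (!is.null(neural)) {
    x <- mat_values(neural)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    xs <- standardize_columns(x, solution$scaling$neural$center,
                              solution$scaling$neural$scale)$values
    out$u <- xs %*% solution$theta
  }
  if (!is.null(symptoms)) {
    y <- mat_values(symptoms)
    if (is.null(dim(y))) y <- matrix(y, nrow = 1)
    ys <- standardize_columns(y, solution$scaling$symptoms$center,
                              solution$scaling$symptoms$scale)$values
    out$v <- ys %*% solution$psi
  }
  out
}

#' Permutation significance of canonical modes with FDR correction
#'
#' Shuffles symptom-set subjects per permutation (breaking the cross-set
#' association while preserving both within-set covariances) and compares
#' each observed canonical correlation with the rank-matched null.
#' Benjamini-Hochberg FDR is applied across modes.
#'
#' @inheritParams fit_cca
#' @param n_perm number of permutations (>= 500).
#' @param seed integer seed.
#' @param fdr_level FDR level for the significance flags (default 0.05).
#' @return list with `pvalues`, `fdr_significant`, `solution`, and the
#'   per-mode permutation null matrix.
#' @export
mode_significance <- function(neural, symptoms, n_perm = 5000L, seed = 1L,
                              fdr_level = 0.05) {
  if (n_perm < 500L) stop("n_perm must be at least 500", call. = FALSE)
  x <- mat_values(neural); y <- mat_values(symptoms)
  sol <- fit_cca(x, y)
  n <- nrow(x); k <- length(sol$canonical_correlations)
  xs <- standardize_columns(x)$values; ys <- standardize_columns(y)$values
  xw <- xs %*% inv_sqrt(crossprod(xs) / (n - 1))
  yw <- ys %*% inv_sqrt(crossprod(ys) / (n - 1))
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      kmat <- crossprod(xw, yw[sample(n), , drop = FALSE]) / (n - 1)
      svd(kmat, nu = 0, nv = 0)$d[seq_len(k)]
    }, numeric(k))
  })
  null_r <- matrix(null_r, nrow = k)
  obs <- sol$canonical_correlations
  pvals <- vapply(seq_len(k), function(m) perm_pvalue(null_r[m, ], obs[m]),
                  numeric(1))
  padj <- stats::p.adjust(pvals, method = "BH")
  list(pvalues = stats::setNames(pvals, names(obs)),
       fdr_significant = stats::setNames(padj < fdr_level, names(obs)),
       fdr_adjusted = stats::setNames(padj, names(obs)),
       solution = sol, null = null_r, n_perm = n_perm)
}

#' Symptom variance explained by the latent neural variates
#'
#' For each neural variate U_k, the proportion of total symptom variance
#' explained is the variance-weighted mean squared correlation between the
#' symptom features and U_k; the total is the sum over modes.
#'
#' @param solution a `cca_solution`.
#' @param symptoms the symptom feature matrix the solution was fitted on
#'   (or compatible new data).
#' @return list with `per_mode` proportions and `total`.
#' @export
variance_explained <- function(solution, symptoms) {
  stopifnot(inherits(solution, "cca_solution"))
  y <- mat_values(symptoms)
  u <- solution$u_scores
  if (nrow(y) != nrow(u))
    stop("symptoms must have the same subjects as the fitted solution",
         call. = FALSE)
  vars <- apply(y, 2, stats::var)
  r2 <- suppressWarnings(stats::cor(y, u))^2
  per_mode <- as.numeric(crossprod(vars, r2)) / sum(vars)
  names(per_mode) <- colnames(u)
  list(per_mode = per_mode, total = sum(per_mode))
}

#' Project canonical symptom-side weights back to original items
#'
#' When the CCA is computed on PC scores, each canonical variate is a
#' linear composite of the PCs; multiplying the PCA item loadings by the
#' CCA symptom-side matrix expresses each variate in terms of the original
#' items.
#'
#' @param cca_psi PCs x modes matrix (symptom-side CCA loadings/weights).
#' @param pca_loadings items x PCs matrix.
#' @return items x modes matrix.
#' @export
project_item_loadings <- function(cca_psi, pca_loadings) {
  cca_psi <- as.matrix(cca_psi); pca_loadings <- as.matrix(pca_loadings)
  if (ncol(pca_loadings) != nrow(cca_psi))
    stop("inner dimensions disagree: ", ncol(pca_loadings), " PCs vs ",
         nrow(cca_psi), call. = FALSE)
  pca_loadings %*% cca_psi
}

#' Leave-one-subject-out prediction of CCA latent scores
#'
#' For each subject, the CCA is refitted on the remaining subjects; the
#' held-out subject's latent scores are computed from the refitted weight
#' matrices. Each leave-one-out fit's modes are sign-aligned with the
#' full-sample solution. The assembled predicted latent matrices are then
#' correlated column-wise: for a stable solution these correlations are
#' comparable to the in-sample canonical correlations, while an overfitted
#' solution collapses toward zero.
#'
#' @inheritParams fit_cca
#' @return list with `predicted_correlations` (per mode, corr of predicted
#'   U-hat and V-hat columns), `u_hat`, `v_hat`, and the full-sample
#'   `solution`.
#' @export
loo_latent_prediction <- function(neural, symptoms) {
  x <- mat_values(neural); y <- mat_values(symptoms)
  full <- fit_cca(x, y)
  n <- nrow(x); k <- length(full$canonical_correlations)
  u_hat <- matrix(NA_real_, n, k); v_hat <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    sol_i <- fit_cca(x[-i, , drop = FALSE], y[-i, , drop = FALSE])
    # sign-align each mode with the full-sample weights
    flip <- sign(colSums(sol_i$theta * full$theta))
    flip[flip == 0] <- 1
    pr <- project_cca(sol_i, neural = x[i, , drop = FALSE],
                      symptoms = y[i, , drop = FALSE])
    u_hat[i, ] <- pr$u * flip
    v_hat[i, ] <- pr$v * flip
  }
  pc <- vapply(seq_len(k), function(m) stats::cor(u_hat[, m], v_hat[, m]),
               numeric(1))
  list(predicted_correlations = stats::setNames(pc, names(full$canonical_correlations)),
       u_hat = u_hat, v_hat = v_hat, solution = full)
}

# ---------------------------------------------------------------------------
# Generative power analysis

#' Generative model encoding a single true canonical mode
#'
#' Builds a joint covariance over p + q features with diagonal within-set
#' covariances (identity, or a power-law eigenvalue spectrum lambda_i
#' proportional to i^-decay) and a rank-one cross-covariance
#' `Sigma_xy = r (Sigma_xx w_x)(Sigma_yy w_y)'` whose canonical correlation
#' is exactly `true_r` with weights `w_x`, `w_y` (drawn once from the seed
#' and normalized to unit variate variance).
#'
#' @param p,q features per set (>= 2).
#' @param true_r true canonical correlation in (0, 1).
#' @param spectrum `"identity"` or `"powerlaw"` within-set covariance.
#' @param decay power-law exponent (default 1).
#' @param seed integer seed for the weight draw.
#' @return list with the joint covariance Cholesky factor, true weights,
#'   true loadings and dimensions; class `cca_power_model`.
#' @export
cca_power_model <- function(p, q, true_r, spectrum = c("identity", "powerlaw"),
                            decay = 1, seed = 1L) {
  spectrum <- match.arg(spectrum)
  if (true_r <= 0 || true_r >= 1) stop("true_r must lie in (0,1)", call. = FALSE)
  if (p < 2L || q < 2L) stop("need at least 2 features per set", call. = FALSE)
  lam_x <- if (spectrum == "identity") rep(1, p) else seq_len(p)^(-decay)
  lam_y <- if (spectrum == "identity") rep(1, q) else seq_len(q)^(-decay)
  w <- with_seed(seed, list(x = stats::rnorm(p), y = stats::rnorm(q)))
  wx <- w$x / sqrt(sum(w$x^2 * lam_x))   # w' Sigma w = 1
  wy <- w$y / sqrt(sum(w$y^2 * lam_y))
  sxx <- diag(lam_x, p); syy <- diag(lam_y, q)
  sxy <- true_r * (lam_x * wx) %*% t(lam_y * wy)
  sigma <- rbind(cbind(sxx, sxy), cbind(t(sxy), syy))
  structure(list(
    chol = chol(sigma), p = p, q = q, true_r = true_r,
    weights = list(x = wx, y = wy),
    loadings = list(x = (lam_x * wx) / sqrt(lam_x),
                    y = (lam_y * wy) / sqrt(lam_y)),
    spectrum = spectrum, decay = decay), class = "cca_power_model")
}

# Internal: first canonical mode of (x, y) plus reusable whitened blocks.
#' @noRd
first_mode <- function(x, y) {
  n <- nrow(x)
  xs <- scale(x); ys <- scale(y)
  wxm <- inv_sqrt(crossprod(xs) / (n - 1))
  wym <- inv_sqrt(crossprod(ys) / (n - 1))
  xw <- xs %*% wxm; yw <- ys %*% wym
  sv <- svd(crossprod(xw, yw) / (n - 1), nu = 1, nv = 1)
  list(r = sv$d[1], wx = as.numeric(wxm %*% sv$u),
       wy = as.numeric(wym %*% sv$v), xw = xw, yw = yw,
       xs = xs, ys = ys, n = n)
}

#' Monte-Carlo CCA estimation quality at a candidate sample size
#'
#' Simulates `n_reps` datasets of size `n` from a [cca_power_model()],
#' fits the first canonical mode of each, and reports permutation power
#' (association strength different from zero at `alpha`) plus the mean of
#' four error metrics relative to the planted truth: relative association
#' error |r_hat - r| / r, weight error 1 - |cos| (worse of the two sets),
#' loading error 1 - |cos| on structure loadings, and score error
#' 1 - |corr| between estimated and true variate scores.
#'
#' @param model a [cca_power_model()].
#' @param n candidate sample size (must exceed p + q).
#' @param n_reps Monte-Carlo replicates.
#' @param n_perm permutations per replicate for the power test.
#' @param alpha test level (default 0.05).
#' @param seed integer seed.
#' @return one-row data.frame: n, power, err_association, err_weight,
#'   err_loading, err_score.
#' @export
estimate_cca_power <- function(model, n, n_reps = 100L, n_perm = 100L,
                               alpha = 0.05, seed = 1L) {
  stopifnot(inherits(model, "cca_power_model"))
  p <- model$p; q <- model$q
  if (n <= p + q + 2L) stop("n too small for CCA", call. = FALSE)
  res <- with_seed(seed, {
    out <- matrix(NA_real_, n_reps, 5)
    for (b in seq_len(n_reps)) {
      z <- matrix(stats::rnorm(n * (p + q)), n) %*% model$chol
      x <- z[, seq_len(p), drop = FALSE]
      y <- z[, p + seq_len(q), drop = FALSE]
      fm <- first_mode(x, y)
      null_r <- vapply(seq_len(n_perm), function(j) {
        svd(crossprod(fm$xw, fm$yw[sample(n), , drop = FALSE]) / (n - 1),
            nu = 0, nv = 0)$d[1]
      }, numeric(1))
      sig <- perm_pvalue(null_r, fm$r) <= alpha
      cosv <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
      w_err <- 1 - min(cosv(fm$wx, model$weights$x),
                       cosv(fm$wy, model$weights$y))
      est_lx <- as.numeric(stats::cor(fm$xs, fm$xs %*% fm$wx))
      est_ly <- as.numeric(stats::cor(fm$ys, fm$ys %*% fm$wy))
      l_err <- 1 - min(cosv(est_lx, model$loadings$x),
                       cosv(est_ly, model$loadings$y))
      s_err <- 1 - min(
        abs(stats::cor(x %*% fm$wx, x %*% model$weights$x)),
        abs(stats::cor(y %*% fm$wy, y %*% model$weights$y)))
      out[b, ] <- c(sig, abs(fm$r - model$true_r) / model$true_r,
                    w_err, l_err, s_err)
    }
    out
  })
  data.frame(n = n, power = mean(res[, 1]),
             err_association = mean(res[, 2]), err_weight = mean(res[, 3]),
             err_loading = mean(res[, 4]), err_score = mean(res[, 5]))
}

#' Required sample size for a stable CCA
#'
#' Determines the smallest sample size, on a geometric grid (factor 1.25),
#' at which permutation power reaches `target_power` and all four error
#' metrics of [estimate_cca_power()] fall to `target_error`, by bisection
#' over the grid (pass/fail is monotone in n).
#'
#' @param n_features_x,n_features_y features per set.
#' @param true_r assumed true canonical correlation in (0, 1).
#' @param target_power required power (default 0.9).
#' @param target_error required error level (default 0.1).
#' @param n_reps Monte-Carlo replicates per grid point (default 100).
#' @param n_perm permutations per replicate (default 100).
#' @param spectrum,decay within-set covariance options, see
#'   [cca_power_model()].
#' @param n_min,n_max search bracket (defaults: just above the feature
#'   count, and 40000).
#' @param alpha test level (default 0.05).
#' @param seed integer seed; every grid point derives a fixed sub-seed.
#' @return list with `n_req`, the evaluated grid rows (`evaluations`), and
#'   the model.
#' @export
required_sample_size <- function(n_features_x, n_features_y, true_r,
                                 target_power = 0.9, target_error = 0.1,
                                 n_reps = 100L, n_perm = 100L,
                                 spectrum = "identity", decay = 1,
                                 n_min = NULL, n_max = 40000L,
                                 alpha = 0.05, seed = 1L) {
  p <- n_features_x; q <- n_features_y
  model <- cca_power_model(p, q, true_r, spectrum = spectrum, decay = decay,
                           seed = sub_seed(seed, 0L))
  if (is.null(n_min)) n_min <- max(16L, ceiling(1.3 * (p + q)))
  grid <- unique(ceiling(n_min * 1.25^(0:ceiling(log(n_max / n_min) / log(1.25)))))
  grid <- grid[grid <= n_max]
  evals <- list()
  passes <- function(i) {
    key <- as.character(grid[i])
    if (is.null(evals[[key]])) {
      evals[[key]] <<- estimate_cca_power(model, grid[i], n_reps = n_reps,
                                          n_perm = n_perm, alpha = alpha,
                                          seed = sub_seed(seed, i))
    }
    e <- evals[[key]]
    e$power >= target_power &&
      max(e$err_association, e$err_weight, e$err_loading, e$err_score) <=
        target_error
  }
  lo <- 1L; hi <- length(grid)
  if (!passes(hi))
    stop("no sample size up to ", grid[hi], " meets the targets; ",
         "bracket [", grid[lo], ", ", grid[hi], "]", call. = FALSE)
  if (passes(lo)) {
    n_req <- grid[lo]
  } else {
    # invariant: lo fails, hi passes
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (passes(mid)) hi <- mid else lo <- mid
    }
    n_req <- grid[hi]
  }
  ev <- do.call(rbind, evals[order(as.numeric(names(evals)))])
  list(n_req = n_req, evaluations = ev, model = model, grid = grid)
}
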