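# Generic resampling harness: leave-site-out, k-fold, split-half,
# leave-one-out, with predicted-vs-observed comparison of any estimator
# exposing fit / project / loadings.

#' Resampling plan
#'
#' @param scheme one of `"kfold"`, `"leave_site_out"`, `"split_half"`,
#'   `"leave_one_out"`.
#' @param k number of folds for `kfold`.
#' @param n_runs number of independent runs (split-half and repeated
#'   k-fold).
#' @param stratify_by optional label name (`"diagnosis"` or `"site"`) used
#'   to preserve group proportions within folds; default `"diagnosis"`
#'   where labels are available.
#' @param seed integer seed.
#' @return object of class `resampling_plan`.
#' @export
resampling_plan <- function(scheme = c("kfold", "leave_site_out",
                                       "split_half", "leave_one_out"),
                            k = 5L, n_runs = 1L,
                            stratify_by = "diagnosis", seed = 1L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, k = as.integer(k),
                 n_runs = as.integer(n_runs), stratify_by = stratify_by,
                 seed = as.integer(seed)), class = "resampling_plan")
}

#' Build train/test index sets for one resampling run
#'
#' Folds are disjoint and exhaustive. Stratified schemes allocate subjects
#' within each stratum round-robin after shuffling, preserving label
#' proportions within plus/minus one subject per label per fold. Split-half
#' is a stratified 2-fold partition. Deterministic given the seed.
#'
#' @param labels data.frame (or list) of per-subject labels; needs a
#'   `site` column for `leave_site_out` and the `stratify_by` column for
#'   stratified schemes. May be `NULL` for unstratified k-fold over
#'   `n_subjects`.
#' @param plan a [resampling_plan()].
#' @param n_subjects required when `labels` is `NULL`.
#' @param run run index (shifts the seed for repeated runs).
#' @return list of `list(train, test)` integer index pairs.
#' @export
make_folds <- function(labels, plan, n_subjects = NULL, run = 1L) {
  stopifnot(inherits(plan, "resampling_plan"))
  if (is.null(labels)) {
    if (is.null(n_subjects)) stop("need labels or n_subjects", call. = FALSE)
    n <- n_subjects
    strata <- rep("all", n)
  } else {
    labels <- as.data.frame(labels)
    n <- nrow(labels)
    strata <- if (!is.null(plan$stratify_by) &&
                  plan$stratify_by %in% names(labels))
      as.character(labels[[plan$stratify_by]]) else rep("all", n)
  }
  seed_run <- sub_seed(plan$seed, run)
  if (plan$scheme == "leave_one_out") {
    return(lapply(seq_len(n), function(i)
      list(train = setdiff(seq_len(n), i), test = i)))
  }
  if (plan$scheme == "leave_site_out") {
    if (is.null(labels) || is.null(labels$site))
      stop("leave_site_out requires a 'site' label", call. = FALSE)
    sites <- unique(as.character(labels$site))
    return(lapply(sites, function(s) {
      test <- which(labels$site == s)
      if (!length(test)) stop("empty site: ", s, call. = FALSE)
      list(train = setdiff(seq_len(n), test), test = test)
    }))
  }
  k <- if (plan$scheme == "split_half") 2L else plan$k
  if (k > n) stop("k exceeds the number of subjects", call. = FALSE)
  tab <- table(strata)
  if (any(tab < k))
    stop("stratum smaller than the number of folds: ",
         paste(names(tab)[tab < k], collapse = ", "), call. = FALSE)
  assign_fold <- integer(n)
  assign_fold <- with_seed(seed_run, {
    af <- integer(n)
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      af[idx] <- rep_len(seq_len(k), length(idx))
    }
    af
  })
  lapply(seq_len(k), function(f)
    list(train = which(assign_fold != f), test = which(assign_fold == f)))
}

#' Predicted-versus-observed stability of an estimator
#'
#' For every fold the estimator is fitted on the training subjects, the
#' held-out subjects are projected, and the predicted held-out scores are
#' correlated with the full-sample observed scores of the same subjects.
#' Components are matched across fits by greedy maximum absolute
#' correlation and sign-aligned.
#'
#' @param estimator list with functions `fit(data, idx)` returning a model,
#'   `project(model, data, idx)` returning a subjects x components score
#'   matrix, and optionally `loadings(model)`. See [pca_estimator()].
#' @param data the data object the estimator understands.
#' @param plan a [resampling_plan()].
#' @param labels per-subject label data.frame (see [make_folds()]).
#' @param n_subjects number of subjects in `data`.
#' @param n_components components to report.
#' @return object of class `stability_report`: per-component `mean`, `se`,
#'   the per-run matrix `runs`, and `n_failed`.
#' @export
predicted_vs_observed <- function(estimator, data, plan, labels = NULL,
                                  n_subjects = NULL, n_components = 5L) {
  full <- estimator$fit(data, NULL)
  obs <- estimator$project(full, data, NULL)
  k_use <- min(n_components, ncol(obs))
  per_run <- list(); n_failed <- 0L
  for (run in seq_len(plan$n_runs)) {
    folds <- make_folds(labels, plan, n_subjects = n_subjects %||% nrow(obs),
                        run = run)
    res <- try({
      fold_cors <- matrix(NA_real_, length(folds), k_use)
      for (fi in seq_along(folds)) {
        f <- folds[[fi]]
        m <- estimator$fit(data, f$train)
        pred <- estimator$project(m, data, f$test)
        mm <- match_components(obs[f$test, seq_len(k_use), drop = FALSE], pred)
        fold_cors[fi, ] <- abs(mm$r[seq_len(k_use)])
      }
      colMeans(fold_cors)
    }, silent = TRUE)
    if (inherits(res, "try-error")) n_failed <- n_failed + 1L
    else per_run[[length(per_run) + 1L]] <- res
  }
  runs <- do.call(rbind, per_run)
  structure(list(mean = colMeans(runs), se = apply(runs, 2, stats::sd) /
                   sqrt(nrow(runs)), runs = runs, n_failed = n_failed,
                 scheme = plan$scheme), class = "stability_report")
}

#' Split-half replication of an estimator
#'
#' Per run, the cohort is split into two disjoint stratified halves, the
#' estimator is fitted independently on each, and similarity is the
#' absolute correlation of greedily matched loading columns (or coefficient
#' maps).
#'
#' @inheritParams predicted_vs_observed
#' @return object of class `stability_report` with per-component mean/se of
#'   matched-loading |r| across runs.
#' @export
split_half_replication <- function(estimator, data, plan, labels = NULL,
                                   n_subjects = NULL, n_components = 5L) {
  if (plan$n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  plan2 <- plan; plan2$scheme <- "split_half"
  per_run <- list(); n_failed <- 0L
  for (run in seq_len(plan$n_runs)) {
    folds <- make_folds(labels, plan2, n_subjects = n_subjects, run = run)
    res <- try({
      m1 <- estimator$fit(data, folds[[1]]$test)
      m2 <- estimator$fit(data, folds[[2]]$test)
      l1 <- estimator$loadings(m1); l2 <- estimator$loadings(m2)
      k_use <- min(n_components, ncol(l1), ncol(l2))
      mm <- match_components(l1[, seq_len(k_use), drop = FALSE], l2)
      abs(mm$r[seq_len(k_use)])
    }, silent = TRUE)
    if (inherits(res, "try-error")) n_failed <- n_failed + 1L
    else per_run[[length(per_run) + 1L]] <- res
  }
  runs <- do.call(rbind, per_run)
  structure(list(mean = colMeans(runs), se = apply(runs, 2, stats::sd) /
                   sqrt(nrow(runs)), runs = runs, n_failed = n_failed,
                 scheme = "split_half"), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report (", x$scheme, "), ", nrow(x$runs), " run(s), ",
      x$n_failed, " failed\n", sep = "")
  cat("per-component mean |r|:", round(x$mean, 3), "\n")
  invisible(x)
}

#' Symptom-PCA estimator for the resampling harness
#'
#' @return estimator list with `fit`, `project`, `loadings` closures over a
#'   subjects x items matrix (or [symptom_matrix()]).
#' @export
pca_estimator <- function() {
  list(
    fit = function(data, idx) {
      x <- mat_values(data)
      if (!is.null(idx)) x <- x[idx, , drop = FALSE]
      fit_pca(x)
    },
    project = function(model, data, idx) {
      x <- mat_values(data)
      if (!is.null(idx)) x <- x[idx, , drop = FALSE]
      project_scores(model, x)
    },
    loadings = function(model) model$loadings)
}

#' Mass-univariate beta-map estimator for the resampling harness
#'
#' `data` must be a list with elements `scores` (subject vector) and `gbc`
#' (subjects x parcels). The "loadings" of a fit are its coefficient map,
#' so split-half replication compares beta maps.
#' @export
betamap_estimator <- function() {
  list(
    fit = function(data, idx) {
      s <- data$scores; g <- mat_values(data$gbc)
      if (!is.null(idx)) { s <- s[idx]; g <- g[idx, , drop = FALSE] }
      map_symptom_to_gbc(s, g)
    },
    project = function(model, data, idx) {
      stop("beta maps have no per-subject projection", call. = FALSE)
    },
    loadings = function(model) matrix(model$coefficients, ncol = 1))
}

#' CCA estimator for the resampling harness
#'
#' `data` must be a list with `neural` and `symptoms` matrices. Loadings
#' reported for split-half comparison are the neural-side structure
#' coefficients (correlations of neural features with their variates).
#' @export
cca_estimator <- function() {
  list(
    fit = function(data, idx) {
      xn <- mat_values(data$neural); xs <- mat_values(data$symptoms)
      if (!is.null(idx)) {
        xn <- xn[idx, , drop = FALSE]; xs <- xs[idx, , drop = FALSE]
      }
      fit_cca(xn, xs)
    },
    project = function(model, data, idx) {
      xn <- mat_values(data$neural)
      if (!is.null(idx)) xn <- xn[idx, , drop = FALSE]
      project_cca(model, neural = xn)$u
    },
    loadings = function(model) model$neural_loadings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
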