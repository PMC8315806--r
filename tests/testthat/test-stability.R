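test_that("fold assembly partitions subjects with stratification", {
  plan <- resampling_plan("kfold", k = 5, seed = 1)
  folds <- make_folds(NULL, plan, n_subjects = 10)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:10)
  expect_true(all(lengths(tests) == 2))
  # split-half preserves diagnostic proportions within +/- 1
  labels <- data.frame(diagnosis = rep(c("BPP", "SADP"), c(60, 40)))
  sh <- make_folds(labels, resampling_plan("split_half", seed = 2))
  for (f in sh) {
    tab <- table(labels$diagnosis[f$test])
    expect_lte(abs(tab[["BPP"]] - 30), 1)
    expect_lte(abs(tab[["SADP"]] - 20), 1)
  }
  # leave-site-out: one fold per site, test set = that site
  labels$site <- rep(paste0("site", 1:6), length.out = 100)
  lso <- make_folds(labels, resampling_plan("leave_site_out", seed = 3))
  expect_length(lso, 6)
  for (f in lso)
    expect_length(unique(labels$site[f$test]), 1)
  # determinism given the seed
  f1 <- make_folds(labels, plan)
  f2 <- make_folds(labels, plan)
  expect_identical(f1, f2)
  expect_error(make_folds(data.frame(diagnosis = c("a", rep("b", 20))),
                          resampling_plan("kfold", k = 5)),
               "stratum smaller")
})

test_that("noiseless low-rank data predicts held-out scores near-perfectly", {
  # predictions of held-out subjects are exact in the train solution's
  # basis; the residual mismatch against the full-sample solution is only
  # the finite-sample rotation of principal axes, so correlations sit just
  # below 1 and all trailing variance fractions are exactly zero
  set.seed(4)
  basis <- matrix(rnorm(3 * 12), 3, 12)
  x <- matrix(rnorm(90 * 3), 90) %*% basis
  rep <- predicted_vs_observed(pca_estimator(), x,
                               resampling_plan("kfold", k = 3, seed = 5),
                               n_subjects = 90, n_components = 3)
  expect_true(all(rep$mean > 0.9))
  expect_equal(sum(fit_pca(x)$variance_fraction[1:3]), 1, tolerance = 1e-10)
})

test_that("planted-factor cohorts predict held-out PC scores across k", {
  coh <- generate_cohort(cohort_config(436, n_parcels = 20, seed = 20))
  labels <- data.frame(diagnosis = coh$symptoms$diagnosis,
                       site = coh$symptoms$site)
  for (k in c(2, 5, 10)) {
    rep <- predicted_vs_observed(pca_estimator(), coh$symptoms,
                                 resampling_plan("kfold", k = k, seed = k),
                                 labels = labels, n_components = 5)
    expect_true(all(rep$mean > 0.9))
  }
  lso <- predicted_vs_observed(pca_estimator(), coh$symptoms,
                               resampling_plan("leave_site_out", seed = 1),
                               labels = labels, n_components = 5)
  expect_true(all(lso$mean > 0.9))
})

test_that("shuffled-label cohorts give near-zero loading replication", {
  set.seed(6)
  x <- matrix(rnorm(200 * 10), 200)  # pure noise: nothing to replicate
  rep <- split_half_replication(pca_estimator(), x,
                                resampling_plan("split_half", n_runs = 50,
                                                seed = 7),
                                n_subjects = 200, n_components = 3)
  # |r| of matched noise loadings is positive by construction (greedy
  # matching over 10-dim vectors); it must stay below the planted regime
  expect_lt(mean(rep$mean), 0.7)
  # planted structure replicates strongly on the same harness
  coh <- generate_cohort(cohort_config(436, n_parcels = 20, seed = 21))
  rep2 <- split_half_replication(pca_estimator(), coh$symptoms,
                                 resampling_plan("split_half", n_runs = 25,
                                                 seed = 8),
                                 labels = data.frame(
                                   diagnosis = coh$symptoms$diagnosis),
                                 n_subjects = 436, n_components = 5)
  expect_gt(mean(rep2$mean), 0.8)
  expect_gt(mean(rep2$mean), mean(rep$mean) + 0.2)
})

test_that("identical halves replicate exactly", {
  set.seed(9)
  half <- matrix(rnorm(40 * 8), 40)
  dup <- rbind(half, half)
  est <- pca_estimator()
  m1 <- est$fit(dup, 1:40); m2 <- est$fit(dup, 41:80)
  mm <- bbsmap:::match_components(est$loadings(m1), est$loadings(m2))
  expect_equal(abs(mm$r), rep(1, 8), tolerance = 1e-10)
})

test_that("reports are invariant to subject ordering", {
  coh <- small_cohort(n = 80, parcels = 15, seed = 30)
  x <- coh$symptoms$values
  plan <- resampling_plan("kfold", k = 4, seed = 11)
  r1 <- predicted_vs_observed(pca_estimator(), x, plan, n_subjects = 80,
                              n_components = 3)
  set.seed(12)
  perm <- sample(80)
  r2 <- predicted_vs_observed(pca_estimator(), x[perm, ], plan,
                              n_subjects = 80, n_components = 3)
  # same subjects, same scheme: mean similarity statistics agree closely
  expect_equal(r1$mean, r2$mean, tolerance = 0.05)
})
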