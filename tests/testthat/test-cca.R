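test_that("fit_cca matches independent oracles on small fixtures", {
  set.seed(1)
  x <- matrix(rnorm(20 * 3), 20); y <- matrix(rnorm(20 * 2), 20)
  sol <- fit_cca(x, y)
  # oracle 1: stats::cancor on standardized data
  oc <- cancor(scale(x), scale(y))
  expect_equal(unname(sol$canonical_correlations), oc$cor, tolerance = 1e-8)
  # oracle 2: generalized eigenproblem for the squared correlations
  sxx <- cov(scale(x)); syy <- cov(scale(y)); sxy <- cov(scale(x), scale(y))
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  ev <- sort(Re(eigen(m)$values), decreasing = TRUE)[1:2]
  expect_equal(unname(sol$canonical_correlations)^2, ev, tolerance = 1e-8)
  # identical sets give all correlations 1
  same <- fit_cca(x, x)
  expect_equal(unname(same$canonical_correlations), rep(1, 3),
               tolerance = 1e-8)
  # invariance to invertible linear maps of one set
  a <- matrix(c(2, 1, 0, 1, 3, 0, 0.5, -1, 1), 3)
  sol2 <- fit_cca(x %*% a, y)
  expect_equal(sol2$canonical_correlations, sol$canonical_correlations,
               tolerance = 1e-8)
})

test_that("cca solution satisfies its structural invariants", {
  set.seed(2)
  x <- matrix(rnorm(60 * 5), 60); y <- matrix(rnorm(60 * 4), 60)
  sol <- fit_cca(x, y)
  k <- 4
  for (m in seq_len(k))
    expect_equal(cor(sol$u_scores[, m], sol$v_scores[, m]),
                 unname(sol$canonical_correlations[m]), tolerance = 1e-10)
  expect_true(all(diff(sol$canonical_correlations) <= 1e-12))
  expect_equal(cov(sol$u_scores), diag(k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(cov(sol$v_scores), diag(k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_cca(matrix(rnorm(10 * 6), 10), matrix(rnorm(10 * 5), 10)),
               "more subjects")
  # rank deficiency is reported with advice
  xdef <- cbind(x, x[, 1])
  expect_error(fit_cca(xdef, y), "rank-deficient")
})

test_that("mode significance flags a planted shared latent and is BH-consistent", {
  set.seed(3)
  n <- 1000
  z <- rnorm(n)
  x <- outer(z, rnorm(6)) + matrix(rnorm(n * 6, sd = 0.5), n)
  y <- outer(z, rnorm(3)) + matrix(rnorm(n * 3, sd = 0.5), n)
  ms <- mode_significance(x, y, n_perm = 500, seed = 4)
  expect_equal(unname(ms$pvalues[1]), 1 / 501)
  expect_true(ms$fdr_significant[1])
  expect_true(all(ms$pvalues > 0 & ms$pvalues <= 1))
  # BH flags are monotone-compatible: a flagged mode never has a larger
  # adjusted p than an unflagged one
  if (any(ms$fdr_significant) && any(!ms$fdr_significant))
    expect_lt(max(ms$fdr_adjusted[ms$fdr_significant]),
              min(ms$fdr_adjusted[!ms$fdr_significant]))
})

test_that("variance explained decomposes symptom variance", {
  set.seed(4)
  x <- matrix(rnorm(100 * 4), 100)
  sol <- fit_cca(x, x)
  ve <- variance_explained(sol, x)
  expect_equal(ve$total, 1, tolerance = 1e-8)
  # independent sets at large n: negligible explained variance per mode
  y <- matrix(rnorm(5000 * 3), 5000)
  x2 <- matrix(rnorm(5000 * 4), 5000)
  ve2 <- variance_explained(fit_cca(x2, y), y)
  expect_true(all(ve2$per_mode < 0.02))
  # hand-computed example: variance-weighted mean squared correlation
  u <- sol$u_scores[, 1]
  vars <- apply(x, 2, var)
  manual <- sum(vars * cor(x, u)^2) / sum(vars)
  expect_equal(unname(ve$per_mode[1]), manual, tolerance = 1e-10)
})

test_that("item loadings project through the PCA basis", {
  set.seed(5)
  pca_l <- matrix(rnorm(36 * 5), 36)
  expect_equal(project_item_loadings(diag(5), pca_l), pca_l)
  psi <- matrix(rnorm(25), 5)
  out <- project_item_loadings(psi, pca_l)
  expect_equal(dim(out), c(36L, 5L))
  expect_equal(out, pca_l %*% psi)
  expect_error(project_item_loadings(matrix(0, 4, 2), pca_l),
               "inner dimensions")
})

test_that("leave-one-out latent prediction detects stability and overfit", {
  set.seed(6)
  # stable regime: strong shared latent, generous n
  n <- 400
  z <- rnorm(n)
  x <- outer(z, rnorm(8)) + matrix(rnorm(n * 8, sd = 1), n)
  y <- outer(z, rnorm(4)) + matrix(rnorm(n * 4, sd = 1), n)
  loo <- loo_latent_prediction(x, y)
  expect_equal(length(loo$predicted_correlations), 4)
  expect_equal(nrow(loo$u_hat), n)
  full_r1 <- loo$solution$canonical_correlations[1]
  expect_lt(abs(loo$predicted_correlations[1] - full_r1), 0.1)
  # overfit regime: independent sets, n barely above p + q; across seeds
  # the in-sample correlation stays inflated while the held-out estimate
  # collapses toward zero
  res <- t(sapply(1:6, function(k) {
    set.seed(100 + k)
    n2 <- 30
    x2 <- matrix(rnorm(n2 * 12), n2); y2 <- matrix(rnorm(n2 * 5), n2)
    c(insample = unname(fit_cca(x2, y2)$canonical_correlations[1]),
      heldout = unname(loo_latent_prediction(x2, y2)$predicted_correlations[1]))
  }))
  expect_gt(min(res[, "insample"]), 0.7)
  expect_lt(abs(mean(res[, "heldout"])), 0.2)
  expect_lt(mean(abs(res[, "heldout"])), mean(res[, "insample"]) - 0.3)
})

test_that("sample canonical correlations are upward-biased at small n", {
  # null configuration with many neural features: the leading sample
  # canonical correlation far exceeds 0 and shrinks with n
  mean_r1 <- sapply(c(200, 1000, 5000), function(n) {
    set.seed(n)
    mean(replicate(3, {
      x <- matrix(rnorm(n * 60), n)
      y <- matrix(rnorm(n * 5), n)
      fit_cca(x, y)$canonical_correlations[1]
    }))
  })
  expect_gt(mean_r1[1], 0.4)
  expect_true(all(diff(mean_r1) < 0))
  expect_lt(mean_r1[3], 0.2)
})
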