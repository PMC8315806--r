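test_that("scrub mask flags threshold breaches plus neighbors", {
  keep <- scrub_mask(c(0.1, 0.6, 0.1, 0.1), rep(1, 4))
  expect_identical(keep, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(scrub_mask(rep(0.2, 6), rep(1, 6))))
  # all frames flagged -> subject exclusion triggers
  ex <- scrub_exclusion(rep(0.6, 4), rep(1, 4))
  expect_equal(ex$flagged_fraction, 1)
  expect_true(ex$exclude)
  # RMS criterion alone flags, with neighbor removal at the boundary
  keep2 <- scrub_mask(rep(0.1, 5), c(1, 1, 1, 1, 10))
  expect_identical(keep2, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # neighbor removal is single-pass, non-cascading
  keep3 <- scrub_mask(c(0.6, 0.1, 0.1, 0.1), rep(1, 4))
  expect_identical(keep3, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(scrub_mask(numeric(0), numeric(0)), "non-empty")
})

test_that("parcellation averages member vertices", {
  # identical series within a parcel pass through unchanged
  s <- matrix(rnorm(20), 1)
  dense <- rbind(s, s, s)
  out <- parcellate(dense, c("a", "a", "a"))
  expect_equal(out["a", ], as.numeric(s))
  # opposite series cancel
  out2 <- parcellate(rbind(s, -s), c("p", "p"))
  expect_equal(max(abs(out2)), 0)
  # random fixture equals brute-force per-parcel means
  set.seed(1)
  dense <- matrix(rnorm(10 * 30), 10)
  assign <- rep(c("x", "y"), each = 5)
  out3 <- parcellate(dense, assign)
  expect_equal(out3["x", ], colMeans(dense[1:5, ]))
  expect_equal(out3["y", ], colMeans(dense[6:10, ]))
  expect_error(parcellate(dense, assign, parcel_ids = c("x", "y", "z")),
               "zero vertices")
})

test_that("GBC equals the brute-force Fisher-z row mean, diagonal excluded", {
  # mutually orthogonal mean-zero series give exactly zero GBC
  s <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1), c(1, 1, -1, -1))
  expect_lt(max(abs(compute_gbc(s))), 1e-12)
  # shift invariance
  set.seed(2)
  x <- matrix(rnorm(5 * 50), 5)
  g1 <- compute_gbc(x)
  x2 <- x; x2[3, ] <- x2[3, ] + 100
  expect_equal(compute_gbc(x2), g1, tolerance = 1e-10)
  # brute-force oracle over the full FC matrix
  oracle <- sapply(1:5, function(p) {
    zs <- sapply(setdiff(1:5, p), function(q) atanh(cor(x[p, ], x[q, ])))
    mean(zs)
  })
  expect_equal(unname(g1), oracle, tolerance = 1e-10)
  # invariance to positive affine rescaling of one parcel
  x3 <- x; x3[2, ] <- 3.7 * x3[2, ] + 2
  expect_equal(compute_gbc(x3), g1, tolerance = 1e-10)
  expect_error(compute_gbc(rbind(x, 0)), "zero-variance parcel")
})

test_that("scrubbing censors by column deletion and feeds GBC", {
  set.seed(3)
  x <- matrix(rnorm(4 * 40), 4)
  keep <- rep(TRUE, 40); keep[c(5, 6, 19)] <- FALSE
  xc <- apply_scrub(x, keep)
  expect_equal(ncol(xc), 37)
  expect_equal(xc, x[, keep])
  expect_error(apply_scrub(x, keep[-1]), "keep_mask")
})

test_that("nuisance regression removes supplied signals", {
  set.seed(4)
  t_len <- 60
  nuis <- cbind(rnorm(t_len), rnorm(t_len))
  clean <- matrix(rnorm(3 * t_len), 3)
  contaminated <- clean + rbind(2 * nuis[, 1], -1.5 * nuis[, 2],
                                nuis[, 1] + nuis[, 2])
  res <- regress_nuisance(contaminated, nuis)
  # residuals orthogonal to the regressors
  expect_lt(max(abs(res %*% nuis)), 1e-8)
  expect_equal(dim(res), dim(contaminated))
})

test_that("cortical symmetrization averages homologue pairs", {
  pairs <- cbind(1:3, 4:6)
  expect_equal(symmetrize_cortex(c(1, 2, 3, 1, 2, 3), pairs), c(1, 2, 3))
  expect_equal(symmetrize_cortex(c(2, 0, 0, 0, 0, 0), pairs), c(1, 0, 0))
  set.seed(5)
  v <- rnorm(6)
  expect_equal(symmetrize_cortex(v, pairs), (v[1:3] + v[4:6]) / 2)
  m <- matrix(rnorm(12), 2)
  expect_equal(symmetrize_cortex(m, pairs), (m[, 1:3] + m[, 4:6]) / 2)
  expect_error(symmetrize_cortex(v, cbind(1:3, c(4, 4, 6))),
               "perfect matching")
})

test_that("parcellating before GBC strengthens planted group statistics", {
  # parcel-homogeneous signal plus vertex noise that is i.i.d. across
  # vertices with subject-varying amplitude (SNR/motion heterogeneity).
  # Averaging vertices before correlating removes the subject-dependent
  # attenuation that otherwise injects symptom-irrelevant between-subject
  # GBC variance, so the symptom association is stronger when
  # parcellating first.
  one_run <- function(seed) {
    set.seed(seed)
    n_sub <- 50; n_parcel <- 5; vps <- 6; t_len <- 100
    assign <- rep(seq_len(n_parcel), each = vps)
    scores <- rnorm(n_sub)
    sigma_i <- runif(n_sub, 0.5, 3)
    z_before <- matrix(NA, n_sub, n_parcel)
    z_after <- matrix(NA, n_sub, n_parcel)
    for (i in seq_len(n_sub)) {
      shared <- rnorm(t_len)
      w <- 1 + 0.2 * scores[i]
      base <- w * matrix(shared, n_parcel, t_len, byrow = TRUE) +
        0.3 * matrix(rnorm(n_parcel * t_len), n_parcel)
      dense <- base[assign, ] +
        matrix(rnorm(n_parcel * vps * t_len, sd = sigma_i[i]),
               n_parcel * vps)
      z_before[i, ] <- compute_gbc(parcellate(dense, assign))
      gbc_dense <- compute_gbc(dense)
      z_after[i, ] <- vapply(seq_len(n_parcel), function(p)
        mean(gbc_dense[assign == p]), numeric(1))
    }
    c(before = abs(map_symptom_to_gbc(scores, z_before)$tvalues[1]),
      after = abs(map_symptom_to_gbc(scores, z_after)$tvalues[1]))
  }
  res <- t(vapply(2:5, one_run, numeric(2)))
  expect_gte(mean(res[, 1] > res[, 2]), 0.75)
  expect_gt(mean(res[, 1] / res[, 2]), 1.1)
})

test_that("per-subject GBC matrices assemble with parcel order preserved", {
  set.seed(7)
  series <- replicate(3, {
    m <- matrix(rnorm(4 * 30), 4)
    rownames(m) <- paste0("p", 1:4)
    m
  }, simplify = FALSE)
  gm <- gbc_from_series(series)
  expect_s3_class(gm, "gbc_matrix")
  expect_equal(dim(gm$values), c(3L, 4L))
  expect_equal(gm$parcel_ids, paste0("p", 1:4))
  expect_equal(gm$values[2, ], compute_gbc(series[[2]]))
})
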