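# Shared fixtures: all synthetic, built in code at test time.

# Small default cohort used across module tests.
small_cohort <- function(n = 150, parcels = 60, seed = 42, ...) {
  generate_cohort(cohort_config(n_subjects = n, n_parcels = parcels,
                                seed = seed, ...))
}

# Planted single-score coupling: gbc = score x map + noise. Signal
# amplitudes are bounded away from zero (magnitude in amp * [0.8, 1.2],
# random sign) so every planted parcel is genuinely detectable.
planted_gbc <- function(n, p, signal_idx, amp = 0.5, noise_sd = 1,
                        seed = 1) {
  set.seed(seed)
  s <- rnorm(n)
  map <- numeric(p)
  k <- length(signal_idx)
  map[signal_idx] <- amp * sample(c(-1, 1), k, TRUE) * runif(k, 0.8, 1.2)
  g <- outer(s, map) + matrix(rnorm(n * p, sd = noise_sd), n, p)
  list(scores = s, gbc = g, map = map)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Tucker-style congruence between the column spaces of two loading
# matrices: mean singular value of Qa' Qb (1 = identical subspaces).
subspace_congruence <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  mean(svd(crossprod(qa, qb))$d)
}
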