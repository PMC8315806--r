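#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic stages draw from seeds derived deterministically from one
#' master seed so that blocks are independently reproducible. Kept below
#' 2^31 - 1 to stay a valid R integer.
#' @noRd
sub_seed <- function(seed, block) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 7919 + block * 104729) %% 2147483647)
}

#' Run code with a local RNG seed, restoring prior RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Column standardization with stored scaling
#'
#' @param x numeric matrix.
#' @param center,scale optional precomputed per-column means / sds.
#' @return list with `values`, `center`, `scale`.
#' @noRd
standardize_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd)
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    bad <- which(!is.finite(scale) | scale <= 0)
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  list(values = sweep(sweep(x, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

#' Fix the sign of each column so its largest-magnitude element is positive
#' @return list(values, flip) where flip is the vector of +/-1 applied.
#' @noRd
fix_column_signs <- function(x) {
  x <- as.matrix(x)
  flip <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    i <- which.max(abs(v))
    if (length(i) && v[i] < 0) -1 else 1
  }, numeric(1))
  list(values = sweep(x, 2, flip, "*"), flip = flip)
}

#' Greedy component matching by maximum absolute correlation
#'
#' Matches columns of `b` to columns of `a`: repeatedly picks the (i, j)
#' pair with the largest |cor(a[,i], b[,j])| among unmatched columns.
#'
#' @return data.frame with columns `a`, `b`, `r` (signed correlation of the
#'   matched pair), one row per matched component.
#' @noRd
match_components <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  k <- min(ncol(a), ncol(b))
  cc <- suppressWarnings(stats::cor(a, b))
  cc[!is.finite(cc)] <- 0
  out <- data.frame(a = integer(k), b = integer(k), r = numeric(k))
  free_a <- rep(TRUE, ncol(a)); free_b <- rep(TRUE, ncol(b))
  for (m in seq_len(k)) {
    sub <- abs(cc)
    sub[!free_a, ] <- -Inf
    sub[, !free_b] <- -Inf
    idx <- arrayInd(which.max(sub), dim(sub))
    out$a[m] <- idx[1]; out$b[m] <- idx[2]; out$r[m] <- cc[idx[1], idx[2]]
    free_a[idx[1]] <- FALSE; free_b[idx[2]] <- FALSE
  }
  out[order(out$a), , drop = FALSE]
}

#' Permutation p-value with the add-one estimator
#' @noRd
perm_pvalue <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}

#' Check a numeric matrix for finiteness
#' @noRd
assert_finite <- function(x, what = "matrix") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
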