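#' Fisher r-to-z transform
#'
#' `fisher_z()` maps a correlation to `atanh(r)`; `inverse_fisher_z()` maps it
#' back with `tanh()`. Correlations are routinely z-transformed before they are
#' averaged across participants or carried into second-level correlations, so
#' that the sampling distribution is approximately normal with
#' variance independent of the true correlation.
#'
#' Inputs with `|r| >= 1` are an error: callers that can legitimately produce
#' exact unity (e.g. a brain model compared with itself) must clip first with
#' [clip_correlation()].
#'
#' @param r correlations, strictly inside (-1, 1).
#' @param z Fisher z values.
#' @return transformed values of the same shape.
#' @examples
#' fisher_z(0.5)
#' inverse_fisher_z(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("fisher_z() requires finite correlations with |r| < 1; clip first.")
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Clip correlations away from +/-1
#'
#' @param r correlations.
#' @param eps distance kept from the boundary (default `1e-6`).
#' @return `r` clamped into `[-(1-eps), 1-eps]`.
#' @export
clip_correlation <- function(r, eps = 1e-6) {
  pmin(pmax(r, -(1 - eps)), 1 - eps)
}

# Deterministic per-stage child seeds from a single pipeline seed.
# stage seed = (seed mod 2e7) * 100 + stage offset, always < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 1L, extract = 2L, connectivity = 3L, gradient = 4L,
    dimensionality = 5L, rsa = 6L, spin = 7L, mediation = 8L, report = 9L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown pipeline stage: ", stage))
  as.integer((as.numeric(seed) %% 2e7) * 100 + offsets[[stage]])
}

# Fix component signs deterministically: flip each column so its first
# element exceeding `tol` in magnitude is positive.
fix_signs <- function(scores, tol = 1e-12) {
  for (k in seq_len(ncol(scores))) {
    v <- scores[, k]
    i <- which(abs(v) > tol)[1]
    if (!is.na(i) && v[i] < 0) scores[, k] <- -v
  }
  scores
}

# Pearson correlation of one vector against each column of a matrix,
# vectorised (used in permutation loops).
cor_vec_mat <- function(x, m) {
  x <- x - mean(x)
  mc <- sweep(m, 2L, colMeans(m))
  num <- drop(crossprod(mc, x))
  den <- sqrt(sum(x^2) * colSums(mc^2))
  num / den
}

# Near-cubic factorisation of n into three integer factors (for tiling
# parcels/voxels on a 3-D grid).
factor3 <- function(n) {
  best <- c(n, 1L, 1L)
  best_score <- Inf
  for (a in seq_len(floor(n^(1 / 3)) + 1L)) {
    if (n %% a != 0) next
    m <- n %/% a
    for (b in seq_len(floor(sqrt(m)) + 1L)) {
      if (m %% b != 0) next
      dims <- sort(c(a, b, m %/% b))
      score <- dims[3] - dims[1]
      if (score < best_score) {
        best <- dims
        best_score <- score
      }
    }
  }
  as.integer(best)
}

# Column-wise Pearson correlation via standardised cross-product (BLAS);
# numerically equivalent to stats::cor on the same input.
cor_cols <- function(m) {
  mc <- sweep(m, 2L, colMeans(m))
  sc <- sqrt(colSums(mc^2))
  crossprod(sweep(mc, 2L, sc, "/"))
}
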