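# Small fixtures shared across test files. Everything is generated in code.

# A tiny but fully structured dataset: enough parcels/trials for every stage
# to run, small enough to be fast.
tiny_spec <- function(...) {
  defaults <- list(
    n_participants = 5, n_trials = 24, n_runs = 3,
    n_parcels = 10, voxels_per_parcel = 8,
    rank_base = 3, rank_weak = 4, rank_strong = 2,
    modulated_parcels = c(7, 9), coupling_parcels = c(8, 10),
    s_lo = 2, s_hi = 4, seed = 42
  )
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(tiny_spec())
    cache
  }
})

# Deterministic toy patterns: trials x voxels with known structure.
toy_patterns <- function(n_trials = 6, n_voxels = 5, seed = 7) {
  set.seed(seed)
  matrix(rnorm(n_trials * n_voxels), n_trials, n_voxels)
}

# Brute-force informational connectivity: explicit double loop over parcel
# pairs, correlation of their vectorised valid-pair similarities.
oracle_ic <- function(similarities, fisher_z = TRUE) {
  mask <- similarities[[1]]$valid_mask
  idx <- which(upper.tri(mask) & mask)
  p <- length(similarities)
  out <- diag(1, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- similarities[[i]]$matrix[idx]
      b <- similarities[[j]]$matrix[idx]
      if (fisher_z) {
        a <- atanh(clip_correlation(a))
        b <- atanh(clip_correlation(b))
      }
      out[i, j] <- out[j, i] <- cor(a, b)
    }
  }
  out
}

# Brute-force Benjamini-Hochberg step-up: reject the p_(1..k*) where k* is
# the largest k with p_(k) <= k q / m.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration with midranks.
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ws <- colSums(matrix(r[combn(n, nx)], nrow = nx))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}
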