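make_rank_data <- function(n_part, n_vox, k, noise_sd = 0, seed = 1,
                           equal_var = TRUE) {
  set.seed(seed)
  u <- qr.Q(qr(matrix(rnorm(n_vox * k), n_vox, k)))
  coef <- matrix(rnorm(n_part * k), n_part, k)
  x <- coef %*% t(u)
  if (noise_sd > 0) x <- x + matrix(rnorm(n_part * n_vox, sd = noise_sd), n_part)
  x
}

test_that("component counting matches the eigen-spectrum oracle", {
  # rank-1: a common pattern times participant scalars
  common <- rnorm(10)
  x <- outer(c(1, 2, 3, -1, 0.5), common)
  expect_equal(count_components(x, 0.9), 1L)

  # k orthogonal planted components, no noise: the count equals the
  # analytic value from the (equal in expectation) spectrum
  for (k in c(3, 5)) {
    x <- make_rank_data(20, 12, k, seed = k)
    d2 <- svd(sweep(x, 2, colMeans(x)))$d^2
    cumfrac <- cumsum(d2) / sum(d2)
    for (th in c(0.6, 0.75, 0.9)) {
      oracle <- which(cumfrac > th)[1]
      expect_equal(count_components(x, th), oracle)
    }
  }

  # threshold 1 returns full rank (strict ">" can never be satisfied)
  x3 <- make_rank_data(20, 12, 3)
  expect_equal(count_components(x3, 1), 3L)
  expect_error(count_components(x3, 0), "threshold")
})

test_that("counts are monotone in threshold and stable under rotation", {
  set.seed(12)
  x <- make_rank_data(15, 10, 4, noise_sd = 0.3)
  c60 <- count_components(x, 0.60)
  c75 <- count_components(x, 0.75)
  c90 <- count_components(x, 0.90)
  expect_true(c60 <= c75 && c75 <= c90)

  # common orthogonal rotation of the voxel axes leaves counts unchanged
  rot <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  for (th in c(0.6, 0.75, 0.9)) {
    expect_equal(count_components(x %*% rot, th), count_components(x, th))
  }
})

test_that("adding isotropic noise never decreases the count", {
  set.seed(30)
  for (k in c(1, 3, 6)) {
    x <- make_rank_data(25, 15, k, seed = k + 100)
    clean <- count_components(x, 0.9)
    noisy <- count_components(
      x + matrix(rnorm(25 * 15, sd = 0.5), 25), 0.9
    )
    expect_gte(noisy, clean)
  }
})

test_that("parcel dimensionality recovers planted per-parcel ranks", {
  sim <- simulate_dataset(synthetic_spec(
    n_participants = 24, n_trials = 12, n_runs = 3, n_parcels = 6,
    voxels_per_parcel = 10, rank_base = 3, rank_weak = 3, rank_strong = 3,
    beta = 0, noise_sd = 1e-4, coef_noise_sd = 1, run_effect_sd = 0,
    global_amp_sd = 0, parcel_amp_sd = 0, seed = 5
  ))
  dm <- parcel_dimensionality(sim$patterns, thresholds = c(0.6, 0.75, 0.9))
  expect_s3_class(dm, "dimensionality_map")
  # at zero noise the 0.9-criterion count equals the planted rank 3, up to
  # the occasional draw whose empirical spectrum crosses the criterion early
  expect_true(all(dm$values[["0.9"]] <= 3L))
  expect_gte(mean(dm$values[["0.9"]] == 3L), 0.95)
  # monotone across thresholds everywhere
  expect_true(all(dm$values[["0.6"]] <= dm$values[["0.75"]]))
  expect_true(all(dm$values[["0.75"]] <= dm$values[["0.9"]]))
})

test_that("searchlight dimensionality works on a voxel grid with skipping", {
  # two participants' patterns over a 6x6x6 grid, rank-2 planted
  dims <- c(6, 6, 6)
  nvox <- prod(dims)
  n_part <- 10
  set.seed(77)
  u <- qr.Q(qr(matrix(rnorm(nvox * 2), nvox, 2)))
  sets <- lapply(seq_len(n_part), function(p) {
    pat <- matrix(rnorm(2 * 2), 2, 2) %*% t(u) # 2 trials
    trial_pattern_set(sprintf("p%02d", p), pat, run_labels = 1:2,
                      trial_ids = c("t1", "t2"))
  })
  res <- searchlight_dimensionality(
    sets, trial = "t1", grid_dim = dims,
    in_mask_voxels = seq_len(nvox), thresholds = 0.9, radius = 2
  )
  # centre voxels away from the edge have full 125-voxel cubes; corner cubes
  # have 27/125 < 50% in-mask and are skipped
  corner <- which(res$centre_voxels == 1)
  expect_true(corner %in% res$skipped)
  middle_lin <- 3 + 2 * 6 + 2 * 36 + 1
  mid_idx <- which(res$centre_voxels == middle_lin)
  expect_false(mid_idx %in% res$skipped)
  expect_equal(res$values[["0.9"]][mid_idx], 2L)
})

test_that("parcel aggregation averages retained centres", {
  atlas <- make_synthetic_atlas(n_parcels = 4, voxels_per_parcel = 27)
  v2p <- voxel_to_parcel(atlas)
  dm <- structure(
    list(
      values = list("0.9" = rep(c(2L, 4L, 6L, 8L), times = 27)[order(rep(1:4, 27))]),
      thresholds = 0.9, kind = "voxel",
      centre_voxels = as.integer(names(sort(v2p))), skipped = integer(0),
      radius = 2
    ),
    class = "dimensionality_map"
  )
  # values constructed so that parcel i has constant count 2i
  labels <- as.vector(atlas$label_volume)[dm$centre_voxels]
  dm$values[["0.9"]] <- labels * 2L
  agg <- parcel_aggregate(dm, atlas)
  expect_equal(agg$value, c(2, 4, 6, 8))
})

test_that("sliding-window profile reduces to the all-trials correlation", {
  set.seed(9)
  pd <- matrix(rpois(8 * 12, 4) + 1, 8, 12,
               dimnames = list(NULL, sprintf("t%02d", 1:12)))
  w2v <- runif(12)
  ref <- rnorm(8)
  prof <- sliding_window_profile(pd, w2v, ref, window = 12)
  expect_equal(nrow(prof$windows), 1)
  expect_equal(prof$windows$r, cor(rowMeans(pd), ref), tolerance = 1e-12)

  prof4 <- sliding_window_profile(pd, w2v, ref, window = 4)
  expect_equal(nrow(prof4$windows), 9)
  expect_error(sliding_window_profile(pd, w2v, ref, window = 13), "window")
})

test_that("the profile trend tracks planted rank decline for strong trials", {
  # dimensionality decreases with association strength only at high-gradient
  # parcels: window correlations grow more negative with word2vec
  p <- 40
  nt <- 60
  g <- seq(-1, 1, length.out = p)
  w2v <- sort(runif(nt))
  set.seed(14)
  base <- matrix(rpois(p * nt, 5), p, nt, dimnames = list(NULL, seq_len(nt)))
  effect <- outer(pmax(g, 0), (w2v - min(w2v)) / diff(range(w2v)) * 6)
  pd <- base - effect
  prof <- sliding_window_profile(pd, w2v, g, window = 4)
  expect_lt(prof$trend_r, 0)
  expect_lt(prof$windows$r[nrow(prof$windows)], prof$windows$r[1])
})

test_that("dimensionality contrast finds planted rank differences", {
  sim <- simulate_dataset(synthetic_spec(
    n_participants = 12, n_trials = 36, n_runs = 3, n_parcels = 8,
    voxels_per_parcel = 10, rank_base = 3, rank_weak = 6, rank_strong = 2,
    modulated_parcels = c(2, 5), beta = 0, noise_sd = 0.1,
    coef_noise_sd = 1, global_amp_sd = 0, parcel_amp_sd = 0, seed = 8
  ))
  dm <- parcel_dimensionality(sim$patterns, thresholds = 0.9)
  ct <- dimensionality_contrast(
    dm, sim$split$weak_ids, sim$split$strong_ids
  )
  expect_true(all(ct$significant[c(2, 5)]))
  expect_true(all(ct$difference[c(2, 5)] > 0))
  expect_error(
    dimensionality_contrast(dm, sim$split$weak_ids, sim$split$weak_ids),
    "disjoint"
  )
})
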