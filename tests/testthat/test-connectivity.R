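test_that("trial similarity is voxelwise Pearson with between-run masking", {
  pat <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1), c(0, 5, 1))
  ts <- trial_similarity(pat, run_labels = c(1, 1, 2, 2))
  expect_equal(ts$matrix[1, 2], 1)
  expect_equal(ts$matrix[1, 3], -1)
  expect_false(any(diag(ts$valid_mask)))
  expect_false(ts$valid_mask[1, 2]) # same run
  expect_true(ts$valid_mask[1, 3]) # between runs
  expect_true(isSymmetric(ts$valid_mask))

  # 6 trials in 3 runs of 2: 12 of the 15 unordered pairs are between-run
  set.seed(3)
  ts6 <- trial_similarity(matrix(rnorm(36), 6), run_labels = rep(1:3, each = 2))
  expect_equal(sum(ts6$valid_mask[upper.tri(ts6$valid_mask)]), 12)

  expect_error(
    trial_similarity(rbind(c(1, 1, 1), c(1, 2, 3)), c(1, 2)),
    "zero-variance trial"
  )
})

test_that("informational connectivity equals the double-loop oracle", {
  set.seed(11)
  runs <- rep(1:3, each = 4)
  sims <- lapply(1:5, function(i) {
    trial_similarity(matrix(rnorm(12 * 6), 12, 6), runs, parcel_id = i)
  })
  for (fz in c(TRUE, FALSE)) {
    ic <- ic_matrix(sims, fisher_z = fz)
    expect_lt(max(abs(unclass(ic) - oracle_ic(sims, fz))), 1e-12)
  }
  ic <- ic_matrix(sims)
  expect_true(isSymmetric(unclass(ic)))
  expect_equal(diag(unclass(ic)), rep(1, 5))
})

test_that("identical and reversed similarity structures give IC +1 / -1", {
  runs <- c(1, 1, 2, 2)
  set.seed(5)
  base <- matrix(rnorm(4 * 6), 4, 6)
  s1 <- trial_similarity(base, runs, parcel_id = 1)
  s2 <- trial_similarity(base + 100, runs, parcel_id = 2) # shifted, same cor
  ic <- ic_matrix(list(s1, s2), fisher_z = FALSE)
  expect_equal(ic[1, 2], 1, tolerance = 1e-10)
})

test_that("IC is invariant to consistent trial permutation and pattern scaling", {
  sim <- tiny_sim()
  ps <- sim$patterns[[1]]
  sims <- parcel_similarities(ps)
  ic <- ic_matrix(sims)

  # consistent permutation of trials across parcels
  perm <- sample(length(ps$trial_ids))
  ps2 <- ps
  ps2$patterns <- ps$patterns[perm, ]
  ps2$run_labels <- ps$run_labels[perm]
  ps2$trial_ids <- ps$trial_ids[perm]
  ic2 <- ic_matrix(parcel_similarities(ps2))
  expect_equal(unclass(ic2), unclass(ic), tolerance = 1e-10)

  # positive scaling + constant shift of one parcel's patterns
  ps3 <- ps
  cols <- which(ps$voxel_to_parcel == 1)
  ps3$patterns[, cols] <- 3.7 * ps3$patterns[, cols] + 11
  ic3 <- ic_matrix(parcel_similarities(ps3))
  expect_equal(unclass(ic3), unclass(ic), tolerance = 1e-10)
})

test_that("group averaging works on the Fisher-z scale", {
  runs <- c(1, 1, 2, 2)
  mk <- function(seed) {
    set.seed(seed)
    lapply(1:3, function(i) {
      trial_similarity(matrix(rnorm(24), 4, 6), runs, parcel_id = i)
    })
  }
  ic1 <- ic_matrix(mk(1))
  ic2 <- ic_matrix(mk(2))
  avg <- group_average(list(ic1, ic2))
  expect_equal(attr(avg, "participant_id"), "group")
  expect_equal(
    avg[1, 2],
    tanh((atanh(ic1[1, 2]) + atanh(ic2[1, 2])) / 2),
    tolerance = 1e-12
  )
  # closed form: r of 0.2 and 0.6 average to tanh(mean(atanh)) = 0.4202
  expect_equal(tanh((atanh(0.2) + atanh(0.6)) / 2), 0.4202, tolerance = 1e-4)
  expect_true(isSymmetric(unclass(avg)))
  # single participant: identity
  single <- group_average(list(ic1))
  expect_equal(as.numeric(single), as.numeric(ic1), tolerance = 1e-12)
  expect_error(group_average(list()), "empty")
})

test_that("time-series connectivity matches hand-computed correlations", {
  set.seed(9)
  s <- matrix(rnorm(30), 10, 3)
  fc <- timeseries_connectivity(s)
  expect_equal(fc[1, 2], cor(s[, 1], s[, 2]), tolerance = 1e-12)
  expect_equal(fc[2, 3], cor(s[, 2], s[, 3]), tolerance = 1e-12)
  ident <- timeseries_connectivity(cbind(s[, 1], s[, 1] + 5))
  expect_equal(ident[1, 2], 1, tolerance = 1e-12)
  neg <- timeseries_connectivity(cbind(s[, 1], -s[, 1]))
  expect_equal(neg[1, 2], -1, tolerance = 1e-12)
  expect_error(timeseries_connectivity(cbind(s[, 1], rep(1, 10))), "constant")
})

test_that("within-run exclusion removes run-effect inflation under the null", {
  # no cross-parcel structure, strong run effects: with the between-run
  # mask the mean off-diagonal IC stays near zero
  set.seed(21)
  runs <- rep(1:3, each = 20)
  sims <- lapply(1:12, function(i) {
    run_eff <- matrix(rnorm(3 * 12, sd = 1.5), 3, 12)
    pat <- matrix(rnorm(60 * 12), 60, 12) + run_eff[runs, ]
    trial_similarity(pat, runs, parcel_id = i)
  })
  ic_masked <- ic_matrix(sims, fisher_z = FALSE)
  off <- ic_masked[upper.tri(ic_masked)]
  expect_lt(abs(mean(off)), 0.02)

  # the same data with the mask disabled (all pairs) shows clear inflation
  sims_all <- lapply(sims, function(s) {
    s$valid_mask <- !diag(nrow(s$matrix)) > 0
    diag(s$valid_mask) <- FALSE
    s
  })
  ic_all <- ic_matrix(sims_all, fisher_z = FALSE)
  expect_gt(mean(ic_all[upper.tri(ic_all)]), mean(off) + 0.05)
})

test_that("IC TSV round-trip preserves values and metadata", {
  sim <- tiny_sim()
  ic <- ic_matrix(parcel_similarities(sim$patterns[[1]]), condition = "all",
                  participant_id = "p01")
  td <- withr::local_tempdir()
  path <- file.path(td, "ic.tsv")
  write_ic_matrix(ic, path, meta = list(seed = 42))
  back <- read_ic_matrix(path)
  expect_lt(max(abs(unclass(back) - unclass(ic))), 1e-12)
  expect_equal(attr(back, "condition"), "all")
  expect_equal(attr(back, "n_valid_pairs"), attr(ic, "n_valid_pairs"))
})
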