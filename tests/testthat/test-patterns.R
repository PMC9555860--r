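test_that("trial extraction averages the window and is linear", {
  # 4-TR toy table, hand-computed means for window {1,2}
  ts <- rbind(
    c(1, 10), # TR 1
    c(3, 20), # TR 2
    c(5, 30), # TR 3
    c(7, 40) # TR 4
  )
  ev <- data.frame(trial_id = c("a", "b"), onset_tr = c(1, 3), run = c(1, 2))
  ps <- extract_trial_patterns(ts, ev, window_trs = 1:2)
  expect_equal(ps$patterns, rbind(c(2, 15), c(6, 35)))

  # constant series: every pattern identically the constant
  const <- extract_trial_patterns(matrix(4, 10, 3), ev, window_trs = 1:2)
  expect_true(all(const$patterns == 4))

  # linearity: extract(A + B) = extract(A) + extract(B)
  set.seed(1)
  a <- matrix(rnorm(40), 4 + 6, 4)
  b <- matrix(rnorm(40), 4 + 6, 4)
  ev2 <- data.frame(trial_id = 1:2, onset_tr = c(1, 5), run = 1:2)
  pa <- extract_trial_patterns(a, ev2, 1:3)$patterns
  pb <- extract_trial_patterns(b, ev2, 1:3)$patterns
  pab <- extract_trial_patterns(a + b, ev2, 1:3)$patterns
  expect_equal(pab, pa + pb, tolerance = 1e-12)
})

test_that("a window that runs off the series names the offending trials", {
  ts <- matrix(0, 6, 2)
  ev <- data.frame(trial_id = c("t1", "t2"), onset_tr = c(1, 5), run = 1:2)
  expect_error(extract_trial_patterns(ts, ev, window_trs = 1:3), "t2")
})

test_that("the semantic window averages three volumes on a 9-TR trial grid", {
  # trials every 9 TRs; window TRs 4-6 picks three volumes per trial
  n_trials <- 4
  ts <- matrix(seq_len(9 * n_trials * 2), 9 * n_trials, 2)
  ev <- data.frame(
    trial_id = seq_len(n_trials),
    onset_tr = (seq_len(n_trials) - 1) * 9 + 1, run = c(1, 1, 2, 2)
  )
  ps <- extract_trial_patterns(ts, ev, window_trs = 4:6)
  for (t in seq_len(n_trials)) {
    rows <- (t - 1) * 9 + 4:6
    expect_equal(ps$patterns[t, ], colMeans(ts[rows, ]))
  }
})

test_that("tercile split is an ordered partition with remainder to the middle", {
  beh <- data.frame(trial_id = 1:6, word2vec = c(.1, .2, .3, .4, .5, .6))
  sp <- split_by_association(beh)
  expect_equal(sort(sp$weak_ids), 1:2)
  expect_equal(sort(sp$strong_ids), 5:6)
  expect_equal(sort(sp$middle_ids), 3:4)

  beh144 <- data.frame(trial_id = 1:144, word2vec = runif(144))
  sp144 <- split_by_association(beh144)
  expect_length(sp144$strong_ids, 48)
  expect_length(sp144$weak_ids, 48)
  expect_setequal(
    c(sp144$strong_ids, sp144$middle_ids, sp144$weak_ids), 1:144
  )

  # remainder goes to the middle tercile
  beh7 <- data.frame(trial_id = 1:7, word2vec = 1:7)
  sp7 <- split_by_association(beh7)
  expect_length(sp7$weak_ids, 2)
  expect_length(sp7$strong_ids, 2)
  expect_length(sp7$middle_ids, 3)

  expect_error(split_by_association(data.frame(trial_id = 1:2, word2vec = 1:2)))
})

test_that("ties at a tercile boundary follow the stable trial-id rule", {
  # all scores tied: assignment must be exactly by trial id order, verified
  # against explicit enumeration of the documented rule
  beh <- data.frame(trial_id = c("c", "a", "b", "e", "d", "f"), word2vec = rep(0.5, 6))
  sp <- split_by_association(beh)
  ids_sorted <- sort(beh$trial_id)
  expect_equal(sp$weak_ids, ids_sorted[1:2])
  expect_equal(sp$middle_ids, ids_sorted[3:4])
  expect_equal(sp$strong_ids, ids_sorted[5:6])
  # permuting row order never changes the assignment
  for (i in 1:5) {
    perm <- beh[sample(6), ]
    spp <- split_by_association(perm)
    expect_equal(spp$weak_ids, sp$weak_ids)
    expect_equal(spp$strong_ids, sp$strong_ids)
  }
})

test_that("response uniqueness counts distinct meanings and proportions", {
  desc <- data.frame(
    trial_id = rep(c("t1", "t2", "t3"), each = 3),
    participant_id = rep(c("p1", "p2", "p3"), 3),
    description = c(
      "Dog!", "dog", "dog ", # one category after normalisation
      "sun", "moon", "star", # three distinct categories
      "link", NA, NA
    )
  )
  res <- suppressWarnings(response_uniqueness(desc))
  tr <- res$trials
  expect_equal(tr$n_unique[tr$trial_id == "t1"], 1L)
  expect_equal(tr$n_unique[tr$trial_id == "t2"], 3L)
  expect_equal(tr$n_unique[tr$trial_id == "t3"], 1L)
  r1 <- res$responses[res$responses$trial_id == "t1", ]
  expect_equal(r1$proportion, 1)
  r2 <- res$responses[res$responses$trial_id == "t2", ]
  expect_equal(r2$proportion, rep(1 / 3, 3))

  # one responder out of 31: proportion 1/31
  solo <- data.frame(trial_id = "t", participant_id = "p1", description = "x")
  res31 <- response_uniqueness(solo, n_participants = 31)
  expect_equal(res31$responses$proportion, 1 / 31, tolerance = 1e-12)

  # a trial with no usable description warns and counts 0
  none <- data.frame(trial_id = "t", participant_id = "p1", description = NA)
  expect_warning(res0 <- response_uniqueness(none), "t")
  expect_equal(res0$trials$n_unique, 0L)
})

test_that("behavioural correlations match closed-form Pearson", {
  beh <- data.frame(
    trial_id = rep(1:6, 2),
    participant_id = rep(c("p1", "p2"), each = 6),
    word2vec = rep(c(.0, .1, .25, .4, .55, .7), 2),
    rating = c(0, 1, 2, 2, 3, 4, 1, 1, 2, 3, 3, 4)
  )
  uniq <- data.frame(trial_id = 1:6, n_unique = c(5, 5, 4, 3, 2, 1))
  res <- behavioral_correlations(beh, uniq)
  mean_rating <- colMeans(matrix(beh$rating, ncol = 6, byrow = TRUE))
  expect_equal(
    res$r[res$measure == "rating_vs_word2vec"],
    cor(mean_rating, c(.0, .1, .25, .4, .55, .7)),
    tolerance = 1e-12
  )
  expect_equal(
    res$r[res$measure == "meanings_vs_word2vec"],
    cor(uniq$n_unique, c(.0, .1, .25, .4, .55, .7)),
    tolerance = 1e-12
  )

  # perfect linear / anti-linear ratings
  beh2 <- data.frame(
    trial_id = 1:5, participant_id = "p1",
    word2vec = seq(0, .4, .1), rating = seq(0, 4)
  )
  expect_equal(behavioral_correlations(beh2)$r, 1, tolerance = 1e-12)
  beh2$rating <- rev(beh2$rating)
  expect_equal(behavioral_correlations(beh2)$r, -1, tolerance = 1e-12)

  beh2$rating <- rep(2, 5)
  expect_error(behavioral_correlations(beh2), "zero-variance")
})
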