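test_that("Fisher z round-trips and rejects |r| >= 1", {
  r <- seq(-0.99, 0.99, length.out = 41)
  expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_error(fisher_z(1), "clip")
  expect_error(fisher_z(-1.2), "clip")
  expect_equal(clip_correlation(1), 1 - 1e-6)
})

test_that("BH-FDR equals the brute-force step-up on exhaustive small inputs", {
  set.seed(41)
  for (rep in 1:200) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 2)
    res <- bh_fdr(p, q = 0.05)
    expect_equal(res$significant, oracle_bh(p, 0.05))
  }
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 5), 0.05)$significant))
  expect_true(bh_fdr(0.04, 0.05)$significant)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Wilcoxon rank-sum matches exact enumeration, including ties", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  # tie-free small samples agree with wilcox.test's exact branch
  set.seed(6)
  for (rep in 1:20) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    x <- rnorm(nx)
    y <- rnorm(ny)
    ours <- wilcoxon_rank_sum(x, y)$p
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }

  # tied samples: exact enumeration with midranks
  for (rep in 1:20) {
    x <- sample(1:3, sample(2:5, 1), replace = TRUE)
    y <- sample(1:3, sample(2:5, 1), replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }

  ident <- wilcoxon_rank_sum(c(2, 2, 2), c(2, 2))
  expect_equal(ident$p, 1)
  expect_true(ident$zero_effect)

  # large samples: tie-corrected normal approximation
  set.seed(61)
  x <- rpois(30, 4)
  y <- rpois(35, 5)
  ours <- wilcoxon_rank_sum(x, y)$p
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("spin permutation p has exact count arithmetic and constant invariance", {
  atlas <- make_synthetic_atlas(60, 4)
  g <- seq(-1, 1, length.out = 60)
  smooth_map <- function(seed) {
    set.seed(seed)
    d <- as.matrix(dist(atlas$centroids))
    l <- t(chol(exp(-d / 0.7) + 1e-8 * diag(60)))
    drop(l %*% rnorm(60))
  }
  a <- smooth_map(1)
  # map vs itself: no rotation reproduces the identity, so p = 1/100
  res <- spin_permutation_test(a, a, atlas$centroids, n_perm = 99, seed = 3)
  expect_equal(res$p_spin, 1 / 100, tolerance = 1e-12)
  expect_equal(res$observed_r, 1)

  # invariance to adding constants to either map
  b <- smooth_map(2)
  r1 <- spin_permutation_test(a, b, atlas$centroids, n_perm = 199, seed = 5)
  r2 <- spin_permutation_test(a + 10, b - 3, atlas$centroids, n_perm = 199, seed = 5)
  expect_equal(r1$p_spin, r2$p_spin, tolerance = 1e-12)
  expect_equal(r1$null_rs, r2$null_rs, tolerance = 1e-12)

  expect_error(
    spin_permutation_test(a, b, atlas$centroids * 2, n_perm = 99),
    "unit-norm"
  )
  expect_error(spin_permutation_test(a, b, atlas$centroids, n_perm = 50), "99")
})

test_that("network contrast flags a planted offset network only", {
  atlas <- make_synthetic_atlas(100, 4)
  set.seed(15)
  vals <- rnorm(100, sd = 0.3)
  vals[atlas$network_labels == "SCN"] <- vals[atlas$network_labels == "SCN"] + 3
  nc <- network_contrast(vals, atlas)
  scn_tests <- nc$tests[nc$tests$network_a == "SCN" | nc$tests$network_b == "SCN", ]
  other_tests <- nc$tests[nc$tests$network_a != "SCN" & nc$tests$network_b != "SCN", ]
  expect_true(all(scn_tests$p_adj < 0.05))
  expect_true(all(other_tests$p_adj > 0.05))
  expect_equal(nrow(nc$networks), 4)

  # identical values: all pairwise p = 1
  flat <- network_contrast(rep(2, 100), atlas)
  expect_true(all(flat$tests$p == 1))
  expect_error(network_contrast(vals, atlas, list(c("SCN", "bogus"))), "bogus")
})

test_that("rm-ANOVA matches the closed-form toy decomposition and aov", {
  # 4 participants x 2 x 2 toy, verified against the cell-mean formulas
  y <- array(0, c(4, 2, 2))
  y[, 1, 1] <- c(3, 4, 5, 6)
  y[, 2, 1] <- c(5, 6, 7, 8)
  y[, 1, 2] <- c(4, 4, 6, 6)
  y[, 2, 2] <- c(9, 8, 7, 10)
  res <- rm_anova_2way(y)
  # independent oracle via stats::aov with within-subject error strata
  df <- expand.grid(participant = factor(1:4), a = factor(1:2), b = factor(1:2))
  df$value <- c(y)
  fit <- summary(stats::aov(value ~ a * b + Error(participant / (a * b)), data = df))
  f_aov <- c(
    fit[["Error: participant:a"]][[1]]["a", "F value"],
    fit[["Error: participant:b"]][[1]]["b", "F value"],
    fit[["Error: participant:a:b"]][[1]]["a:b", "F value"]
  )
  expect_equal(res$F, unname(f_aov), tolerance = 1e-10)
  # two-level factors: sphericity trivially holds, epsilon = 1
  expect_equal(res$epsilon, rep(1, 3))
  expect_true(all(res$pes >= 0 & res$pes <= 1))

  # factor B constant: its main effect F ~ 0
  y0 <- y
  y0[, , 2] <- y0[, , 1]
  res0 <- rm_anova_2way(y0)
  f_b <- res0$F[res0$effect == "b"]
  expect_true(is.nan(f_b) || f_b < 1e-10) # 0/0 when the factor is constant

  expect_error(rm_anova_2way(array(c(y[, , 1], NA), c(4, 2, 2))), "missing|complete")
})

test_that("rm-ANOVA agrees with aov on larger random designs and GG epsilon <= 1", {
  set.seed(51)
  for (rep in 1:3) {
    n <- 6
    a <- 3
    b <- 4
    y <- array(rnorm(n * a * b), c(n, a, b)) +
      outer(rnorm(n), array(1, c(a, b))) # participant offsets
    res <- rm_anova_2way(y)
    df <- expand.grid(
      participant = factor(1:n), a = factor(1:a), b = factor(1:b)
    )
    df$value <- c(y)
    fit <- summary(stats::aov(value ~ a * b + Error(participant / (a * b)), data = df))
    f_aov <- c(
      fit[["Error: participant:a"]][[1]]["a", "F value"],
      fit[["Error: participant:b"]][[1]]["b", "F value"],
      fit[["Error: participant:a:b"]][[1]]["a:b", "F value"]
    )
    expect_equal(res$F, unname(f_aov), tolerance = 1e-8)
    expect_true(all(res$epsilon <= 1 + 1e-12))
    expect_true(all(res$epsilon >= 1 / c(a - 1, b - 1, (a - 1) * (b - 1))))
  }
})

test_that("mediation recovers exact algebra on noiseless data", {
  set.seed(99)
  x <- rnorm(50)
  m <- x + rnorm(50, sd = 1e-3) # identified limit of full mediation
  y <- m # y = m exactly: b = 1 and c' = 0 hold exactly
  res <- mediation(x, m, y, n_boot = 200, seed = 1)
  expect_equal(unname(res$paths["a"]), 1, tolerance = 1e-3)
  expect_equal(unname(res$paths["b"]), 1, tolerance = 1e-8)
  expect_equal(unname(res$paths["c_prime"]), 0, tolerance = 1e-8)
  expect_equal(res$proportion_mediated, 1, tolerance = 1e-8)
})

test_that("mediation paths match lm and satisfy c = c' + a*b", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 60
    x <- rnorm(n)
    m <- 0.5 * x + rnorm(n)
    y <- 0.3 * x + 0.6 * m + rnorm(n)
    res <- mediation(x, m, y, n_boot = 50, seed = rep)
    expect_equal(unname(res$paths["a"]), unname(coef(lm(m ~ x))[2]), tolerance = 1e-10)
    fit2 <- coef(lm(y ~ x + m))
    expect_equal(unname(res$paths["c_prime"]), unname(fit2["x"]), tolerance = 1e-10)
    expect_equal(unname(res$paths["b"]), unname(fit2["m"]), tolerance = 1e-10)
    expect_equal(
      unname(res$paths["c"]),
      unname(res$paths["c_prime"] + res$paths["a"] * res$paths["b"]),
      tolerance = 1e-8
    )
  }
})

test_that("a null mediator yields an indirect CI containing zero", {
  set.seed(81)
  x <- rnorm(100)
  m <- rnorm(100) # independent of x and y
  y <- 0.4 * x + rnorm(100)
  res <- mediation(x, m, y, n_boot = 500, seed = 9)
  expect_true(res$ci_low <= 0 && res$ci_high >= 0)
  expect_error(mediation(rep(1, 20), rnorm(20), rnorm(20), 10), "zero-variance")
})
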