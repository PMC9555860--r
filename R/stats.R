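#' Spin permutation test for parcel maps on a sphere
#'
#' Tests the correlation between two spatially autocorrelated parcel maps
#' against a null built by rigidly rotating one map over the sphere: each of
#' `n_perm` uniformly random 3-D rotations is applied to the parcel
#' centroids, each original parcel inherits the value of the nearest rotated
#' centroid, and the map correlation is recomputed. Rotation preserves the
#' map's spatial autocorrelation, which an exchangeability-based permutation
#' would destroy. The p value is two-tailed:
#' `p = (1 + #\{|r_null| >= |r_obs|\}) / (1 + n_perm)`.
#'
#' @param map_a,map_b per-parcel numeric maps.
#' @param sphere_coords P x 3 unit-norm centroid coordinates.
#' @param n_perm number of random rotations (>= 99; the conventional default
#'   is 5000).
#' @param seed rotation seed (recorded on the result).
#' @param method correlation method.
#' @return object of class `spin_null`: list with `observed_r`, `null_rs`,
#'   `p_spin`, `n_perm`, `seed`.
#' @export
spin_permutation_test <- function(map_a, map_b, sphere_coords,
                                  n_perm = 5000, seed = 1L,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  sphere_coords <- as.matrix(sphere_coords)
  if (length(map_a) != nrow(sphere_coords) || length(map_b) != nrow(sphere_coords)) {
    abort("maps and centroid coordinates differ in length.")
  }
  if (n_perm < 99) abort("n_perm must be >= 99.")
  norms <- sqrt(rowSums(sphere_coords^2))
  if (any(abs(norms - 1) > 1e-6)) abort("centroids must be unit-norm.")
  observed <- cor(map_a, map_b, method = method)
  if (method == "spearman") {
    ra <- rank(map_a)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  null_rs <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    rot <- random_rotation()
    rotated <- sphere_coords %*% t(rot)
    # nearest rotated centroid (max cosine) for each original parcel
    nn <- max.col(sphere_coords %*% t(rotated), ties.method = "first")
    perm_b <- map_b[nn]
    null_rs[k] <- if (method == "spearman") {
      cor(ra, rank(perm_b))
    } else {
      cor(map_a, perm_b)
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  p <- (1 + sum(abs(null_rs) >= abs(observed))) / (1 + n_perm)
  structure(
    list(
      observed_r = observed, null_rs = null_rs, p_spin = p,
      n_perm = n_perm, seed = seed, method = method
    ),
    class = "spin_null"
  )
}

# Uniform random rotation in SO(3) via QR of a Gaussian matrix with sign
# correction (Stewart's method).
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @export
print.spin_null <- function(x, ...) {
  cat(
    "<spin_null> r = ", sprintf("%.3f", x$observed_r),
    ", p_spin = ", format.pval(x$p_spin), " (", x$n_perm, " rotations)\n",
    sep = ""
  )
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment with a rejection mask at level `q`.
#'
#' @param p_values p values in `[0, 1]` (non-empty).
#' @param q FDR level.
#' @return tibble with `p`, `p_adj`, `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) abort("empty p value vector.")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p = p_values, p_adj = adj, significant = !is.na(adj) & adj <= q)
}

#' Wilcoxon rank-sum test (exact under ties for small samples)
#'
#' Two-sided rank-sum test. For `n_x + n_y <= 12` the null distribution of
#' the rank sum is enumerated exactly over all group assignments using
#' midranks, so the exact branch remains valid for tied data (where the
#' standard implementation falls back to an approximation). Larger samples
#' use the tie-corrected normal approximation. Identical samples return
#' `p = 1` with a zero-effect flag rather than an error.
#'
#' @param x,y numeric samples with >= 2 observations each.
#' @return one-row tibble: `statistic` (rank sum W of `x`), `df` (`NA`),
#'   `p`, `effect_size` (rank-biserial correlation), `method`,
#'   `zero_effect`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) abort("both samples need >= 2 observations.")
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  rb <- 1 - 2 * u / (nx * ny) # rank-biserial (positive when x tends smaller)
  if (length(unique(pooled)) == 1L) {
    return(tibble(
      statistic = w, df = NA_real_, p = 1, effect_size = 0,
      method = "degenerate", zero_effect = TRUE
    ))
  }
  n <- nx + ny
  if (n <= 12) {
    sets <- combn(n, nx)
    ws <- colSums(matrix(r[sets], nrow = nx))
    p_lo <- mean(ws <= w)
    p_hi <- mean(ws >= w)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  tibble(
    statistic = w, df = NA_real_, p = p, effect_size = rb,
    method = method, zero_effect = FALSE
  )
}

#' Network-level contrast of a parcel map
#'
#' Summarises a per-parcel map within each functional network (mean and
#' standard error across parcels) and runs the configured pairwise
#' comparisons (Welch t tests across parcels) with Bonferroni adjustment.
#'
#' @param parcel_map tibble with `parcel` and `value`, or a numeric vector
#'   in atlas parcel order.
#' @param atlas a [parcellation_atlas()] supplying network labels.
#' @param comparisons optional list of 2-element character vectors; default
#'   all pairs of the contrast networks present (excluding `"other"`).
#' @return list with `networks` (tibble: `network`, `n`, `mean`, `se`) and
#'   `tests` (tibble: `network_a`, `network_b`, `statistic`, `df`, `p`,
#'   `p_adj`).
#' @export
network_contrast <- function(parcel_map, atlas, comparisons = NULL) {
  values <- if (is.data.frame(parcel_map)) {
    parcel_map[["value"]] %||% parcel_map[["difference"]]
  } else {
    parcel_map
  }
  if (length(values) != n_parcels(atlas)) {
    abort("map length does not match the atlas.")
  }
  nets <- atlas$network_labels
  use <- nets != "other"
  lv <- unique(nets[use])
  if (length(lv) < 2) abort("need at least 2 networks with parcels.")
  if (!is.null(comparisons)) {
    unknown <- setdiff(unlist(comparisons), nets)
    if (length(unknown) > 0) {
      abort(paste0("unknown network name(s): ", paste(unknown, collapse = ", ")))
    }
  } else {
    comparisons <- combn(lv, 2, simplify = FALSE)
  }
  summaries <- tibble(
    network = lv,
    n = vapply(lv, function(nm) sum(nets == nm), integer(1)),
    mean = vapply(lv, function(nm) mean(values[nets == nm]), numeric(1)),
    se = vapply(lv, function(nm) {
      v <- values[nets == nm]
      sd(v) / sqrt(length(v))
    }, numeric(1))
  )
  tests <- purrr::map_dfr(comparisons, function(cmp) {
    a <- values[nets == cmp[1]]
    b <- values[nets == cmp[2]]
    if (sd(c(a, b)) == 0) {
      return(tibble(
        network_a = cmp[1], network_b = cmp[2],
        statistic = 0, df = NA_real_, p = 1
      ))
    }
    tt <- t.test(a, b)
    tibble(
      network_a = cmp[1], network_b = cmp[2],
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value
    )
  })
  tests$p_adj <- pmin(1, tests$p * nrow(tests))
  list(networks = summaries, tests = tests)
}

# Greenhouse-Geisser epsilon from an n x levels matrix of within-subject
# scores (one column per level of the effect).
gg_epsilon <- function(scores) {
  a <- ncol(scores)
  if (a <= 2) return(1)
  s <- stats::cov(scores)
  cmat <- stats::contr.helmert(a)
  cmat <- qr.Q(qr(cmat)) # orthonormal contrasts
  m <- t(cmat) %*% s %*% cmat
  sum(diag(m))^2 / ((a - 1) * sum(m^2))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Both factors within-subject, complete balanced design. Returns F,
#' Greenhouse-Geisser-corrected (possibly fractional) degrees of freedom and
#' p value, partial eta squared, and the epsilon for each main effect and
#' the interaction. With two levels sphericity is trivial and epsilon is 1.
#'
#' @param data data frame with columns `participant`, `a`, `b`, `value`, or
#'   a 3-D array participants x levels(A) x levels(B).
#' @return tibble with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `pes` (partial eta squared), `epsilon`.
#' @export
rm_anova_2way <- function(data) {
  if (is.data.frame(data)) {
    pts <- sort(unique(data$participant))
    la <- sort(unique(data$a))
    lb <- sort(unique(data$b))
    y <- array(NA_real_, dim = c(length(pts), length(la), length(lb)))
    for (r in seq_len(nrow(data))) {
      y[
        match(data$participant[r], pts), match(data$a[r], la),
        match(data$b[r], lb)
      ] <- data$value[r]
    }
  } else {
    y <- data
  }
  if (anyNA(y)) abort("missing cells: the design must be complete and balanced.")
  n <- dim(y)[1]
  a <- dim(y)[2]
  b <- dim(y)[3]
  if (n < 2 || a < 2 || b < 2) abort("need >= 2 participants and >= 2 levels per factor.")
  grand <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
    outer(rep(1, a), m_b) + grand)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
    outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
    outer(rep(1, n), m_b) + grand)^2)
  resid <- y
  for (i in seq_len(n)) {
    for (j in seq_len(a)) {
      for (k in seq_len(b)) {
        resid[i, j, k] <- y[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
          m_s[i] + m_a[j] + m_b[k] - grand
      }
    }
  }
  ss_abs <- sum(resid^2)

  eps_a <- gg_epsilon(m_sa)
  eps_b <- gg_epsilon(m_sb)
  # interaction contrasts: (a-1)(b-1)-dimensional double-centred cell scores
  inter <- matrix(NA_real_, n, a * b)
  for (i in seq_len(n)) inter[i, ] <- as.vector(y[i, , ])
  ca <- qr.Q(qr(stats::contr.helmert(a)))
  cb <- qr.Q(qr(stats::contr.helmert(b)))
  cab <- kronecker(cb, ca) # matches as.vector(y[i, , ]) layout (a fast)
  s_int <- t(cab) %*% stats::cov(inter) %*% cab
  eps_ab <- if (nrow(s_int) == 1) 1 else {
    sum(diag(s_int))^2 / (nrow(s_int) * sum(s_int^2))
  }

  row_for <- function(effect, ss_eff, df1, ss_err, df2, eps) {
    f <- (ss_eff / df1) / (ss_err / df2)
    p <- pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
    tibble(
      effect = effect, F = f, df1 = df1 * eps, df2 = df2 * eps, p = p,
      pes = ss_eff / (ss_eff + ss_err), epsilon = eps
    )
  }
  dplyr::bind_rows(
    row_for("a", ss_a, a - 1, ss_as, (a - 1) * (n - 1), eps_a),
    row_for("b", ss_b, b - 1, ss_bs, (b - 1) * (n - 1), eps_b),
    row_for("a:b", ss_ab, (a - 1) * (b - 1), ss_abs, (a - 1) * (b - 1) * (n - 1), eps_ab)
  )
}

# OLS path coefficients for the three mediation regressions (with
# intercepts): m ~ x, y ~ x + m, y ~ x.
mediation_paths <- function(x, m, y) {
  sxx <- sum((x - mean(x))^2)
  sxm <- sum((x - mean(x)) * (m - mean(m)))
  smm <- sum((m - mean(m))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  smy <- sum((m - mean(m)) * (y - mean(y)))
  a <- sxm / sxx
  det <- sxx * smm - sxm^2
  if (det <= 1e-12 * sxx * smm) {
    abort("mediator is (numerically) collinear with the predictor.")
  }
  c_prime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  c_total <- sxy / sxx
  c(a = a, b = b, c_prime = c_prime, c = c_total)
}

#' Bootstrap mediation analysis
#'
#' Simple three-variable mediation with observation units resampled with
#' replacement (here, parcels): path `a` (`m ~ x`), paths `b` and `c'`
#' (`y ~ x + m`), total effect `c` (`y ~ x`), indirect effect `a * b` with a
#' percentile bootstrap confidence interval, and proportion mediated
#' `a * b / c`. The OLS identity `c = c' + a * b` holds exactly.
#'
#' @param x,m,y equal-length numeric vectors (n >= 10): predictor, mediator,
#'   outcome.
#' @param n_boot bootstrap resamples (the conventional default is 5000).
#' @param seed bootstrap seed.
#' @param conf confidence level of the percentile interval.
#' @return object of class `mediation_result`: list with `paths` (named
#'   vector `a`, `b`, `c_prime`, `c`), `indirect`, `ci_low`, `ci_high`,
#'   `boot_indirect`, `boot_se`, `boot_paths` (bootstrap draws of every
#'   path), `boot_path_se`, `proportion_mediated`, `p_boot` (two-sided
#'   sign-flip proportion of the bootstrap distribution), `n`, `n_boot`,
#'   `seed`.
#' @export
mediation <- function(x, m, y, n_boot = 5000, seed = 1L, conf = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n) abort("x, m, y must have equal length.")
  if (n < 10) abort("need at least 10 observations.")
  if (sd(x) == 0) abort("zero-variance predictor.")
  paths <- mediation_paths(x, m, y)
  indirect <- paths[["a"]] * paths[["b"]]
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  boot_paths <- matrix(NA_real_, n_boot, 4,
                       dimnames = list(NULL, c("a", "b", "c_prime", "c")))
  for (k in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_paths[k, ] <- mediation_paths(x[idx], m[idx], y[idx])
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  boot <- boot_paths[, "a"] * boot_paths[, "b"]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  p_boot <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  structure(
    list(
      paths = paths, indirect = indirect,
      ci_low = ci[1], ci_high = ci[2],
      boot_indirect = boot, boot_se = sd(boot),
      boot_paths = boot_paths,
      boot_path_se = apply(boot_paths, 2, sd),
      proportion_mediated = indirect / paths[["c"]],
      p_boot = min(1, p_boot),
      n = n, n_boot = n_boot, seed = seed, conf = conf
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  p <- x$paths
  cat(
    "<mediation_result> a = ", sprintf("%.4f", p[["a"]]),
    ", b = ", sprintf("%.4f", p[["b"]]),
    ", c' = ", sprintf("%.4f", p[["c_prime"]]),
    ", c = ", sprintf("%.4f", p[["c"]]), "\n  indirect a*b = ",
    sprintf("%.4f", x$indirect), " [", sprintf("%.4f", x$ci_low), ", ",
    sprintf("%.4f", x$ci_high), "] (", x$n_boot, " bootstrap samples)\n",
    "  proportion mediated = ", sprintf("%.3f", x$proportion_mediated), "\n",
    sep = ""
  )
  invisible(x)
}
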