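#' Count components needed to exceed a variance criterion
#'
#' Core of the dimensionality estimator: given a participants x voxels
#' matrix for one trial and location, columns are mean-centred and the
#' number of principal components whose cumulative variance exceeds
#' (strictly) the threshold is returned. With `threshold = 1` this is the
#' matrix rank (strict ">" can never be met, so the full rank is returned).
#'
#' @param x numeric matrix, participants x voxels (>= 2 participants).
#' @param threshold variance criterion in (0, 1].
#' @return integer component count.
#' @export
count_components <- function(x, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1].")
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("fewer than 2 participants.")
  xc <- sweep(x, 2L, colMeans(x))
  d2 <- svd(xc, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) return(1L)
  cumfrac <- cumsum(d2) / tot
  m <- which(cumfrac > threshold)[1]
  if (is.na(m)) m <- sum(d2 > max(d2) * 1e-12) # threshold 1: full rank
  as.integer(m)
}

# Vectorised variant over several thresholds sharing one spectrum.
count_components_multi <- function(x, thresholds) {
  x <- as.matrix(x)
  xc <- sweep(x, 2L, colMeans(x))
  d2 <- svd(xc, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) return(rep(1L, length(thresholds)))
  cumfrac <- cumsum(d2) / tot
  rank_full <- sum(d2 > max(d2) * 1e-12)
  vapply(thresholds, function(th) {
    m <- which(cumfrac > th)[1]
    if (is.na(m)) rank_full else as.integer(m)
  }, integer(1))
}

#' Parcel-wise neural dimensionality per trial
#'
#' For every parcel and trial, stacks all participants' voxel patterns into
#' a participants x voxels matrix and applies [count_components()]: the
#' resulting map indexes the complexity (latent dimensionality) of the local
#' neural representation for that trial.
#'
#' @param pattern_sets list of [trial_pattern_set()] (one per participant,
#'   same trials and voxel layout).
#' @param thresholds variance criteria; the canonical criterion is 0.9, with
#'   0.6 and 0.75 used for robustness checks.
#' @return object of class `dimensionality_map`: list with `values` (named
#'   list, one parcels x trials integer matrix per threshold), `thresholds`,
#'   `kind = "parcel"`, `trial_ids`, `parcel_ids`.
#' @export
parcel_dimensionality <- function(pattern_sets, thresholds = 0.9) {
  if (length(pattern_sets) < 2) abort("fewer than 2 participants.")
  v2p <- pattern_sets[[1]]$voxel_to_parcel
  if (is.null(v2p)) abort("pattern sets carry no voxel_to_parcel map.")
  trial_ids <- pattern_sets[[1]]$trial_ids
  for (ps in pattern_sets) {
    if (!identical(ps$trial_ids, trial_ids)) abort("trial ids differ across participants.")
  }
  ids <- sort(unique(v2p))
  nt <- length(trial_ids)
  vals <- lapply(thresholds, function(th) {
    matrix(NA_integer_, length(ids), nt, dimnames = list(NULL, trial_ids))
  })
  names(vals) <- as.character(thresholds)
  cols_by_parcel <- lapply(ids, function(i) which(v2p == i))
  for (pi in seq_along(ids)) {
    cols <- cols_by_parcel[[pi]]
    stacks <- lapply(pattern_sets, function(ps) ps$patterns[, cols, drop = FALSE])
    for (t in seq_len(nt)) {
      x <- t(vapply(stacks, function(m) m[t, ], numeric(length(cols))))
      cts <- count_components_multi(x, thresholds)
      for (j in seq_along(thresholds)) vals[[j]][pi, t] <- cts[j]
    }
  }
  structure(
    list(
      values = vals, thresholds = thresholds, kind = "parcel",
      trial_ids = trial_ids, parcel_ids = ids, radius = NA_integer_
    ),
    class = "dimensionality_map"
  )
}

#' Searchlight neural dimensionality for one trial
#'
#' Voxel-level variant: a cube of edge `2 * radius + 1` voxels is centred on
#' every in-mask voxel of a 3-D grid; participants' patterns over the cube
#' voxels are stacked and [count_components()] applied. Centres whose cube
#' has fewer than `min_fraction` of its voxels in-mask are skipped and
#' reported.
#'
#' @param pattern_sets list of [trial_pattern_set()] whose columns are
#'   linear indices of `grid_dim` (column `j` = voxel `in_mask_voxels[j]`).
#' @param trial trial id or index to analyse.
#' @param grid_dim integer length-3 grid dimensions.
#' @param in_mask_voxels linear indices of in-mask voxels, in pattern-column
#'   order.
#' @param thresholds variance criteria.
#' @param radius cube half-width in voxels (default 2: a 5 x 5 x 5 cube of
#'   125 voxels).
#' @param min_fraction minimum in-mask fraction of cube voxels (default 0.5).
#' @return object of class `dimensionality_map` with `kind = "voxel"`:
#'   `values` holds one length-`n_centres` integer vector per threshold
#'   (`NA` for skipped centres), plus `skipped` centre indices.
#' @export
searchlight_dimensionality <- function(pattern_sets, trial, grid_dim,
                                       in_mask_voxels, thresholds = 0.9,
                                       radius = 2, min_fraction = 0.5) {
  if (length(pattern_sets) < 2) abort("fewer than 2 participants.")
  nvox <- length(in_mask_voxels)
  trial_idx <- if (is.character(trial)) {
    match(trial, pattern_sets[[1]]$trial_ids)
  } else {
    as.integer(trial)
  }
  if (is.na(trial_idx)) abort("unknown trial.")
  col_of <- rep(NA_integer_, prod(grid_dim))
  col_of[in_mask_voxels] <- seq_len(nvox)
  coords <- arrayInd(in_mask_voxels, grid_dim)
  edge <- 2L * radius + 1L
  offs <- as.matrix(expand.grid(
    dx = -radius:radius, dy = -radius:radius, dz = -radius:radius
  ))
  rows <- t(vapply(
    pattern_sets, function(ps) ps$patterns[trial_idx, ], numeric(nvox)
  ))
  n_cube <- edge^3
  vals <- lapply(thresholds, function(th) rep(NA_integer_, nvox))
  names(vals) <- as.character(thresholds)
  skipped <- integer(0)
  for (ci in seq_len(nvox)) {
    cube <- sweep(offs, 2L, coords[ci, ], "+")
    ok <- cube[, 1] >= 1 & cube[, 1] <= grid_dim[1] &
      cube[, 2] >= 1 & cube[, 2] <= grid_dim[2] &
      cube[, 3] >= 1 & cube[, 3] <= grid_dim[3]
    lin <- cube[ok, 1] + (cube[ok, 2] - 1L) * grid_dim[1] +
      (cube[ok, 3] - 1L) * grid_dim[1] * grid_dim[2]
    cols <- col_of[lin]
    cols <- cols[!is.na(cols)]
    if (length(cols) < min_fraction * n_cube) {
      skipped <- c(skipped, ci)
      next
    }
    cts <- count_components_multi(rows[, cols, drop = FALSE], thresholds)
    for (j in seq_along(thresholds)) vals[[j]][ci] <- cts[j]
  }
  structure(
    list(
      values = vals, thresholds = thresholds, kind = "voxel",
      trial_ids = pattern_sets[[1]]$trial_ids[trial_idx],
      centre_voxels = in_mask_voxels, skipped = skipped, radius = radius
    ),
    class = "dimensionality_map"
  )
}

#' Aggregate a voxel dimensionality map to parcels
#'
#' Mean of retained centre-voxel counts within each parcel of an atlas.
#' Parcels with no retained centre get `NA` (reported via a message).
#'
#' @param dim_map a voxel-kind `dimensionality_map`.
#' @param atlas a [parcellation_atlas()].
#' @param threshold which stored threshold to aggregate (default the first).
#' @return tibble with `parcel`, `value`.
#' @export
parcel_aggregate <- function(dim_map, atlas, threshold = NULL) {
  if (dim_map$kind != "voxel") abort("parcel_aggregate() needs a voxel-kind map.")
  th <- as.character(threshold %||% dim_map$thresholds[1])
  counts <- dim_map$values[[th]]
  labels <- as.vector(atlas$label_volume)[dim_map$centre_voxels]
  out <- tibble(parcel = atlas$parcel_ids, value = NA_real_)
  for (k in seq_along(out$parcel)) {
    sel <- labels == out$parcel[k] & !is.na(counts)
    if (any(sel)) out$value[k] <- mean(counts[sel])
  }
  if (anyNA(out$value)) {
    message(
      "parcel(s) with no retained searchlight centre: ",
      paste(out$parcel[is.na(out$value)], collapse = ", ")
    )
  }
  out
}

#' Sliding-window dimensionality-gradient profile
#'
#' Orders trials by ascending association score, averages the per-parcel
#' dimensionality over every consecutive window of `window` trials, and
#' correlates each window-averaged map with a reference gradient. The trend
#' statistic is the correlation of the per-window map correlation against
#' the window-mean association score — negative when the
#' dimensionality-gradient coupling grows more negative for stronger
#' associations.
#'
#' @param parcel_dim parcels x trials matrix (or `dimensionality_map` of
#'   parcel kind; first threshold used).
#' @param word2vec per-trial association scores (pattern column order).
#' @param reference_gradient per-parcel reference map.
#' @param window trials per window (>= 2, <= number of trials); windows
#'   slide by one trial.
#' @param method correlation method for the per-window map correlation.
#' @return list with `windows` (tibble: `window`, `mean_word2vec`, `r`),
#'   `trend_r`, `trend_p`.
#' @export
sliding_window_profile <- function(parcel_dim, word2vec, reference_gradient,
                                   window = 4, method = "pearson") {
  if (inherits(parcel_dim, "dimensionality_map")) {
    parcel_dim <- parcel_dim$values[[1]]
  }
  nt <- ncol(parcel_dim)
  if (window < 2) abort("window must be >= 2.")
  if (window > nt) abort("window exceeds the number of trials.")
  o <- order(word2vec)
  pd <- parcel_dim[, o, drop = FALSE]
  w <- word2vec[o]
  n_win <- nt - window + 1
  rs <- numeric(n_win)
  mw <- numeric(n_win)
  for (k in seq_len(n_win)) {
    cols <- k:(k + window - 1)
    avg <- rowMeans(pd[, cols, drop = FALSE])
    rs[k] <- if (sd(avg) == 0) NA_real_ else {
      cor(avg, reference_gradient, method = method)
    }
    mw[k] <- mean(w[cols])
  }
  trend_r <- NA_real_
  trend_p <- NA_real_
  ok <- !is.na(rs)
  if (sum(ok) >= 3 && sd(rs[ok]) > 0 && sd(mw[ok]) > 0) {
    ct <- suppressWarnings(cor.test(rs[ok], mw[ok]))
    trend_r <- unname(ct$estimate)
    trend_p <- ct$p.value
  }
  list(
    windows = tibble(window = seq_len(n_win), mean_word2vec = mw, r = rs),
    trend_r = trend_r, trend_p = trend_p
  )
}

#' Dimensionality contrast between weak and strong associations
#'
#' Per location, the difference in mean dimensionality between weak and
#' strong trials (weak minus strong — the direction in which higher counts
#' are expected for weakly associated pairs), a two-sided Wilcoxon rank-sum
#' test across trials, and a Benjamini-Hochberg FDR mask at level `q`.
#'
#' @param parcel_dim parcels x trials matrix (or parcel-kind
#'   `dimensionality_map`; first threshold used).
#' @param weak_ids,strong_ids disjoint non-empty trial-id sets (column
#'   names) with >= 2 trials each.
#' @param q FDR level (default 0.05).
#' @return tibble with `parcel`, `difference`, `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
dimensionality_contrast <- function(parcel_dim, weak_ids, strong_ids, q = 0.05) {
  if (inherits(parcel_dim, "dimensionality_map")) {
    parcel_dim <- parcel_dim$values[[1]]
  }
  if (length(intersect(weak_ids, strong_ids)) > 0) {
    abort("weak and strong trial sets must be disjoint.")
  }
  if (length(weak_ids) < 2 || length(strong_ids) < 2) {
    abort("each trial set needs at least 2 trials.")
  }
  wi <- match(as.character(weak_ids), colnames(parcel_dim))
  si <- match(as.character(strong_ids), colnames(parcel_dim))
  if (anyNA(wi) || anyNA(si)) abort("unknown trial ids in contrast sets.")
  p_vals <- numeric(nrow(parcel_dim))
  stat <- numeric(nrow(parcel_dim))
  diff_ <- numeric(nrow(parcel_dim))
  for (i in seq_len(nrow(parcel_dim))) {
    wv <- parcel_dim[i, wi]
    sv <- parcel_dim[i, si]
    diff_[i] <- mean(wv) - mean(sv)
    res <- wilcoxon_rank_sum(wv, sv)
    p_vals[i] <- res$p
    stat[i] <- res$statistic
  }
  fdr <- bh_fdr(p_vals, q)
  tibble(
    parcel = seq_len(nrow(parcel_dim)),
    difference = diff_, statistic = stat,
    p = p_vals, p_adj = fdr$p_adj, significant = fdr$significant
  )
}
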