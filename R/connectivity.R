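#' Between-trial pattern similarity within a parcel
#'
#' Correlates every pair of trial patterns across voxels, giving a trials x
#' trials similarity matrix, together with a validity mask that excludes the
#' diagonal and all within-run pairs (within-run pairs share slow temporal
#' autocorrelation and would inflate similarity estimates).
#'
#' @param patterns numeric matrix, trials x voxels (>= 2 voxels).
#' @param run_labels run of each trial.
#' @param method `"pearson"` (default, matches downstream Fisher-z use) or
#'   `"spearman"`.
#' @param parcel_id optional parcel identifier carried on the result.
#' @return object of class `trial_similarity`: list with `matrix` (symmetric,
#'   unit diagonal), `valid_mask` (symmetric logical, `FALSE` diagonal and
#'   within-run pairs), `run_labels`, `parcel_id`.
#' @examples
#' pat <- matrix(rnorm(40), nrow = 4)
#' ts <- trial_similarity(pat, run_labels = c(1, 1, 2, 2))
#' sum(ts$valid_mask) / 2 # between-run unordered pairs
#' @export
trial_similarity <- function(patterns, run_labels,
                             method = c("pearson", "spearman"),
                             parcel_id = NA_integer_) {
  method <- match.arg(method)
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2) abort("at least 2 voxels are required.")
  centred <- patterns - rowMeans(patterns)
  ss <- rowSums(centred^2)
  if (any(ss == 0)) {
    abort(paste0(
      "zero-variance trial pattern(s): ",
      paste(which(ss == 0), collapse = ", ")
    ))
  }
  s <- if (method == "pearson") {
    # row-standardised cross-product: exact Pearson across voxels
    sm <- tcrossprod(centred / sqrt(ss))
    diag(sm) <- 1
    sm
  } else {
    cor(t(patterns), method = method)
  }
  mask <- outer(run_labels, run_labels, "!=")
  diag(mask) <- FALSE
  structure(
    list(
      matrix = s, valid_mask = mask,
      run_labels = as.integer(run_labels), parcel_id = parcel_id
    ),
    class = "trial_similarity"
  )
}

# Upper-triangle indices of the valid (between-run) pairs of a mask.
valid_pair_index <- function(mask) {
  which(upper.tri(mask) & mask)
}

#' Informational connectivity matrix
#'
#' Correlates the between-trial similarity structures of every pair of
#' parcels: entry (i, j) is the Pearson correlation between parcel i's and
#' parcel j's vectorised valid-pair similarities (within-run pairs excluded).
#' Optionally the similarity values are Fisher z-transformed first (the
#' default, since all correlations in this pipeline are z-transformed before
#' being carried forwards). The diagonal is set to 1.
#'
#' @param similarities list of [trial_similarity()] objects, one per parcel,
#'   all sharing the same trials and validity mask.
#' @param fisher_z transform similarity values with `atanh` before
#'   correlating (default `TRUE`).
#' @param condition,participant_id metadata carried on the result
#'   (`participant_id = "group"` marks a group matrix).
#' @return object of class `ic_matrix`: a P x P symmetric matrix with
#'   attributes `condition`, `participant_id`, `n_valid_pairs`, `parcel_ids`.
#' @export
ic_matrix <- function(similarities, fisher_z = TRUE,
                      condition = "all", participant_id = NA_character_) {
  if (length(similarities) < 2) abort("need at least 2 parcels.")
  mask <- similarities[[1]]$valid_mask
  for (s in similarities) {
    if (!identical(dim(s$matrix), dim(mask)) || !identical(s$valid_mask, mask)) {
      abort("all parcels must share trial ids and the same valid_mask.")
    }
  }
  idx <- valid_pair_index(mask)
  if (length(idx) < 3) abort("fewer than 3 valid (between-run) trial pairs.")
  vals <- vapply(similarities, function(s) s$matrix[idx], numeric(length(idx)))
  if (fisher_z) vals <- atanh(clip_correlation(vals))
  cm <- colMeans(vals)
  const <- which(colSums((vals - rep(cm, each = nrow(vals)))^2) == 0)
  if (length(const) > 0) {
    ids <- vapply(similarities[const], function(s) as.character(s$parcel_id), "")
    abort(paste0(
      "constant similarity vector for parcel(s): ",
      paste(ifelse(is.na(ids), as.character(const), ids), collapse = ", ")
    ))
  }
  m <- cor_cols(vals)
  diag(m) <- 1
  pids <- vapply(similarities, function(s) as.integer(s$parcel_id), integer(1))
  structure(
    m,
    condition = condition, participant_id = participant_id,
    n_valid_pairs = length(idx), parcel_ids = pids,
    class = c("ic_matrix", "matrix", "array")
  )
}

#' Group-average informational connectivity
#'
#' Element-wise mean of per-participant matrices on the Fisher-z scale,
#' back-transformed with `tanh` (or a plain mean of raw correlations with
#' `fisher_z = FALSE`). The diagonal is reset to 1 and the participant id is
#' `"group"`.
#'
#' @param ic_list non-empty list of `ic_matrix` objects with identical
#'   dimensions and condition.
#' @param fisher_z average on the z scale (default `TRUE`).
#' @return an `ic_matrix` with `participant_id = "group"`.
#' @examples
#' # two participants with r = 0.2 and 0.6 average to tanh(mean(atanh(r)))
#' @export
group_average <- function(ic_list, fisher_z = TRUE) {
  if (length(ic_list) == 0) abort("empty list of connectivity matrices.")
  d <- dim(ic_list[[1]])
  conds <- unique(vapply(ic_list, function(m) attr(m, "condition"), ""))
  if (length(conds) != 1) abort("matrices mix conditions.")
  for (m in ic_list) {
    if (!identical(dim(m), d)) abort("matrices differ in size.")
  }
  acc <- Reduce(`+`, lapply(ic_list, function(m) {
    z <- unclass(m)
    if (fisher_z) atanh(clip_correlation(z)) else z
  })) / length(ic_list)
  out <- if (fisher_z) tanh(acc) else acc
  diag(out) <- 1
  structure(
    out,
    condition = conds, participant_id = "group",
    n_valid_pairs = attr(ic_list[[1]], "n_valid_pairs"),
    parcel_ids = attr(ic_list[[1]], "parcel_ids"),
    class = c("ic_matrix", "matrix", "array")
  )
}

#' Time-series functional connectivity (control analysis)
#'
#' The conventional connectivity measure informational connectivity is
#' compared against: the Pearson correlation of parcel-averaged time series
#' between every pair of parcels.
#'
#' @param mean_series numeric matrix, time points x parcels (each column a
#'   parcel's averaged series).
#' @param condition,participant_id metadata for the result.
#' @return an `ic_matrix`-shaped correlation matrix.
#' @export
timeseries_connectivity <- function(mean_series, condition = "all",
                                    participant_id = NA_character_) {
  mean_series <- as.matrix(mean_series)
  const <- which(apply(mean_series, 2, sd) == 0)
  if (length(const) > 0) {
    abort(paste0("constant time series for parcel(s): ", paste(const, collapse = ", ")))
  }
  m <- cor(mean_series)
  diag(m) <- 1
  structure(
    m,
    condition = condition, participant_id = participant_id,
    n_valid_pairs = nrow(mean_series),
    parcel_ids = seq_len(ncol(mean_series)),
    class = c("ic_matrix", "matrix", "array")
  )
}

#' Per-parcel trial similarities for one participant
#'
#' Convenience wrapper: splits a [trial_pattern_set()] into parcels and
#' computes [trial_similarity()] for each, optionally restricted to a subset
#' of trials.
#'
#' @param pattern_set a [trial_pattern_set()].
#' @param trial_ids optional subset of trials (e.g. one association tercile).
#' @param method correlation method passed to [trial_similarity()].
#' @return list of [trial_similarity()] objects in parcel-id order.
#' @export
parcel_similarities <- function(pattern_set, trial_ids = NULL,
                                method = "pearson") {
  stopifnot(inherits(pattern_set, "trial_pattern_set"))
  v2p <- pattern_set$voxel_to_parcel
  if (is.null(v2p)) abort("pattern set has no voxel_to_parcel map.")
  keep <- if (is.null(trial_ids)) {
    seq_along(pattern_set$trial_ids)
  } else {
    match(trial_ids, pattern_set$trial_ids)
  }
  if (any(is.na(keep))) abort("unknown trial ids requested.")
  runs <- pattern_set$run_labels[keep]
  ids <- sort(unique(v2p))
  lapply(ids, function(i) {
    trial_similarity(
      pattern_set$patterns[keep, v2p == i, drop = FALSE],
      run_labels = runs, method = method, parcel_id = i
    )
  })
}

#' Restrict a trial similarity to a subset of trials
#'
#' Subsetting the similarity matrix and validity mask to a trial subset is
#' exactly equivalent to recomputing the similarity on those trials, since
#' each entry depends only on its own pair of patterns.
#'
#' @param ts a [trial_similarity()].
#' @param idx integer indices of the trials to keep.
#' @return a [trial_similarity()] over the subset.
#' @export
subset_similarity <- function(ts, idx) {
  structure(
    list(
      matrix = ts$matrix[idx, idx, drop = FALSE],
      valid_mask = ts$valid_mask[idx, idx, drop = FALSE],
      run_labels = ts$run_labels[idx],
      parcel_id = ts$parcel_id
    ),
    class = "trial_similarity"
  )
}

#' Per-participant informational connectivity for a trial subset
#'
#' Runs [parcel_similarities()] then [ic_matrix()] for every participant and
#' returns the list of per-participant matrices (use [group_average()] to
#' pool them). When several conditions are needed from the same patterns,
#' pass precomputed all-trial similarities via `sims_full` so the
#' trial-pair correlations are computed once and subset per condition.
#'
#' @param pattern_sets list of [trial_pattern_set()] objects.
#' @param trial_ids optional trial subset defining the condition.
#' @param condition condition label.
#' @param fisher_z passed to [ic_matrix()].
#' @param sims_full optional list (one element per participant) of
#'   [parcel_similarities()] over all trials.
#' @return list of `ic_matrix` objects.
#' @export
ic_per_participant <- function(pattern_sets, trial_ids = NULL,
                               condition = "all", fisher_z = TRUE,
                               sims_full = NULL) {
  lapply(seq_along(pattern_sets), function(pi) {
    ps <- pattern_sets[[pi]]
    sims <- if (is.null(sims_full)) {
      parcel_similarities(ps, trial_ids = trial_ids)
    } else if (is.null(trial_ids)) {
      sims_full[[pi]]
    } else {
      idx <- match(trial_ids, ps$trial_ids)
      if (anyNA(idx)) abort("unknown trial ids requested.")
      lapply(sims_full[[pi]], subset_similarity, idx = idx)
    }
    ic_matrix(
      sims,
      fisher_z = fisher_z, condition = condition,
      participant_id = ps$participant_id
    )
  })
}
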