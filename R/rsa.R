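#' Inter-participant semantic similarity model
#'
#' Correlates participants' ratings of associative strength across trials:
#' entry (p, q) is the Pearson correlation between participant p's and q's
#' rating vectors, capturing how similarly the two experienced the stimuli.
#'
#' @param ratings numeric matrix, participants x trials (>= 3 participants).
#' @return object of class `participant_similarity`: correlation matrix with
#'   attribute `kind = "semantic"`.
#' @export
semantic_model <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 3) abort("need at least 3 participants.")
  sds <- apply(ratings, 1, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "constant rating vector for participant(s): ",
      paste(rownames(ratings)[sds == 0] %||% which(sds == 0), collapse = ", ")
    ))
  }
  m <- unname(cor(t(ratings)))
  diag(m) <- 1
  structure(m, kind = "semantic", location = NA_integer_,
            class = c("participant_similarity", "matrix", "array"))
}

#' Inter-participant brain similarity model at one location
#'
#' For one parcel (or searchlight), vectorises each participant's valid
#' (between-run) trial-pair similarities and correlates these vectors across
#' participants: entry (p, q) is high when the two participants' local
#' representational geometries agree.
#'
#' @param trial_sims list of [trial_similarity()] objects, one per
#'   participant, sharing the same validity mask.
#' @param location location identifier stored on the result.
#' @return `participant_similarity` matrix with `kind = "brain"`.
#' @export
brain_model <- function(trial_sims, location = NA_integer_) {
  if (length(trial_sims) < 3) abort("need at least 3 participants.")
  mask <- trial_sims[[1]]$valid_mask
  idx <- valid_pair_index(mask)
  if (length(idx) < 3) abort("fewer than 3 valid trial pairs.")
  vals <- vapply(trial_sims, function(s) {
    if (!identical(s$valid_mask, mask)) {
      abort("participants must share the same valid_mask.")
    }
    s$matrix[idx]
  }, numeric(length(idx)))
  m <- cor(vals)
  diag(m) <- 1
  structure(m, kind = "brain", location = location,
            class = c("participant_similarity", "matrix", "array"))
}

lower_tri <- function(m) m[lower.tri(m)]

#' Second-order semantic-brain alignment
#'
#' Correlates the lower triangles (diagonal excluded) of the semantic model
#' and each location's brain model, giving a per-location alignment value on
#' the Fisher-z scale. Correlations are clipped to `1 - 1e-6` in magnitude
#' before the z transform so the equality edge case stays finite. Degenerate
#' (constant) brain models yield `NA` and are reported.
#'
#' @param semantic a [semantic_model()].
#' @param brain_models named list of [brain_model()]s (one per location).
#' @return tibble (`alignment_map`): `location`, `r`, `z`.
#' @export
second_order_alignment <- function(semantic, brain_models) {
  sem_lt <- lower_tri(unclass(semantic))
  out <- purrr::imap_dfr(brain_models, function(bm, loc) {
    if (nrow(bm) != nrow(semantic)) abort("participant sets differ.")
    bl <- lower_tri(unclass(bm))
    r <- if (sd(bl) == 0 || sd(sem_lt) == 0) NA_real_ else cor(sem_lt, bl)
    tibble(location = loc, r = r)
  })
  if (anyNA(out$r)) {
    message(
      "degenerate brain model at location(s): ",
      paste(out$location[is.na(out$r)], collapse = ", ")
    )
  }
  out$z <- ifelse(is.na(out$r), NA_real_, atanh(clip_correlation(out$r)))
  out$location <- if (all(grepl("^[0-9]+$", out$location))) {
    as.integer(out$location)
  } else {
    out$location
  }
  out
}

#' Permutation significance of semantic-brain alignment
#'
#' Mantel-style participant permutation test: participant-pair entries of a
#' similarity model are not independent, so a parametric correlation test
#' would be invalid. Rows and columns of the semantic model are permuted
#' simultaneously `n_perm` times; per location,
#' `p = (1 + #\{|z_perm| >= |z_obs|\}) / (1 + n_perm)`, followed by
#' Benjamini-Hochberg FDR at level `q`.
#'
#' @param semantic a [semantic_model()].
#' @param brain_models named list of [brain_model()]s.
#' @param n_perm permutations (>= 99; conventional default 5000).
#' @param q FDR level.
#' @param seed permutation seed.
#' @return tibble: `location`, `r`, `z`, `p`, `p_adj`, `significant`.
#' @export
alignment_significance <- function(semantic, brain_models, n_perm = 5000,
                                   q = 0.05, seed = 1L) {
  if (n_perm < 99) abort("n_perm must be >= 99.")
  obs <- second_order_alignment(semantic, brain_models)
  np <- nrow(semantic)
  bmat <- vapply(brain_models, function(bm) lower_tri(unclass(bm)),
                 numeric(np * (np - 1) / 2))
  sem <- unclass(semantic)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  exceed <- rep(0, nrow(obs))
  obs_abs <- abs(obs$z)
  for (k in seq_len(n_perm)) {
    perm <- sample.int(np)
    sem_lt <- lower_tri(sem[perm, perm])
    rp <- cor_vec_mat(sem_lt, bmat)
    zp <- atanh(clip_correlation(rp))
    exceed <- exceed + as.numeric(abs(zp) >= obs_abs)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  obs$p <- (1 + exceed) / (1 + n_perm)
  obs$p[is.na(obs$z)] <- NA_real_
  fdr <- bh_fdr(ifelse(is.na(obs$p), 1, obs$p), q)
  obs$p_adj <- ifelse(is.na(obs$p), NA_real_, fdr$p_adj)
  obs$significant <- !is.na(obs$p) & fdr$significant
  obs
}

#' Brain models for every parcel of a dataset
#'
#' Convenience wrapper: computes each participant's per-parcel trial
#' similarities once, then builds a [brain_model()] per parcel.
#'
#' @param pattern_sets list of [trial_pattern_set()].
#' @param trial_ids optional trial subset.
#' @param sims_full optional precomputed all-trial [parcel_similarities()]
#'   per participant (reused, and subset if `trial_ids` is given).
#' @return named list of `participant_similarity` matrices (names =
#'   parcel ids).
#' @export
parcel_brain_models <- function(pattern_sets, trial_ids = NULL,
                                sims_full = NULL) {
  sims <- if (is.null(sims_full)) {
    lapply(pattern_sets, parcel_similarities, trial_ids = trial_ids)
  } else if (is.null(trial_ids)) {
    sims_full
  } else {
    lapply(seq_along(pattern_sets), function(pi) {
      idx <- match(trial_ids, pattern_sets[[pi]]$trial_ids)
      lapply(sims_full[[pi]], subset_similarity, idx = idx)
    })
  }
  ids <- vapply(sims[[1]], function(s) s$parcel_id, integer(1))
  out <- lapply(seq_along(ids), function(pi) {
    brain_model(lapply(sims, `[[`, pi), location = ids[pi])
  })
  names(out) <- ids
  out
}
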