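#' Specification of a synthetic dataset
#'
#' Describes a parcellated multi-participant dataset with planted ground
#' truth, emulating the design of a slow event-related semantic association
#' experiment: 31 participants, 144 word-pair trials in 3 contiguous runs,
#' an association (word2vec) score per trial drawn over the stimulus range
#' `[-0.05, 0.72]`, and integer 0-4 link-strength ratings that track the
#' association score with participant-specific noise.
#'
#' Four effects are planted, each recoverable by one downstream stage:
#'
#' * a 1-D latent gradient `g*` over parcels: the cross-parcel correlation
#'   of the shared latent trial coordinates decays exponentially with
#'   gradient distance `|g*_i - g*_j|`, so between-parcel sharing of
#'   trial-level similarity structure follows `g*`;
#' * condition modulation: the decay rate interpolates with the trial's
#'   word2vec score from `s_hi` (weakest association; short-range sharing)
#'   down to `s_lo` (strongest; long-range sharing). With `s_hi > s_lo`,
#'   strongly associated trials organise informational connectivity
#'   coherently over longer gradient distances, which strengthens the
#'   recovered principal gradient -- the strong-minus-weak difference of
#'   principal-gradient scores tracks `g*` when the gradient is oriented
#'   with transmodal cortex positive;
#' * latent rank: the participant-level deviations around the shared trial
#'   coordinates span `rank_map[parcel, condition]` latent components. The
#'   cross-participant centring of the dimensionality estimator removes the
#'   shared coordinates exactly, so the estimator sees precisely the
#'   planted rank while the trial-similarity structure (which drives the
#'   gradient) stays condition-clean -- each planted effect is recovered by
#'   its own stage without disturbing the others;
#' * rating-brain coupling: in `coupling_parcels`, a pattern component
#'   whose trial course is the participant's standardised rating vector
#'   (strength `beta`) is added along a fixed parcel direction, so
#'   participants with more similar ratings have more similar local
#'   representational geometry. Coupling acts on patterns, not on
#'   similarities, so second-order RSA must genuinely recover it. Strong
#'   coupling necessarily also adds shared similarity structure among the
#'   coupled parcels (they all encode the rating course), so the default
#'   strength is kept moderate to leave the connectivity gradient clean.
#'
#' A matched "chevron" control pattern set is generated from the same
#' machinery with the condition modulation held constant at the midpoint of
#' `s_lo` and `s_hi` and a condition-independent rank, mirroring a task
#' period where the semantic manipulation should not bite.
#'
#' @param n_participants,n_trials,n_runs design size; `n_trials` must be a
#'   multiple of `n_runs` (runs are contiguous equal blocks).
#' @param n_parcels,voxels_per_parcel atlas size.
#' @param planted_gradient per-parcel latent axis in `[-1, 1]`; default
#'   equally spaced.
#' @param s_lo,s_hi decay rate of the cross-parcel latent correlation
#'   `exp(-rate * |g_i - g_j|)` at the strongest (`s_lo`) and weakest
#'   (`s_hi`) association score; `s_hi >= s_lo >= 0`. `s_hi > s_lo` encodes
#'   the directional hypothesis (stronger associations share similarity
#'   structure over longer gradient range); equality gives a null dataset.
#' @param rank_base latent rank outside modulated parcels (all conditions).
#' @param rank_weak,rank_strong latent rank inside `modulated_parcels` for
#'   weak/strong trials (middle trials use `rank_base`).
#' @param modulated_parcels indices of rank-modulated parcels. `NULL`
#'   (default) plants a graded profile over the transmodal half: the
#'   weak/strong ranks interpolate from `rank_base` at `g* <= 0` to
#'   `rank_weak`/`rank_strong` at the apex.
#' @param coupling_parcels indices of rating-coupled parcels. `NULL`
#'   (default) grades the coupling strength as `beta * max(g*, 0)`.
#' @param beta coupling strength (0 disables coupling).
#' @param noise_sd isotropic voxel noise sd.
#' @param coef_noise_sd participant-level sd around the shared latent trial
#'   coordinates (sets single-trial cross-participant spread).
#' @param run_effect_sd sd of a run-constant additive pattern per
#'   (participant, parcel, run); creates the within-run similarity inflation
#'   that between-run pair exclusion is there to remove.
#' @param rating_noise_sd sd of participant rating noise (rating scale units).
#' @param global_amp_sd sd of a per-trial global activation amplitude shared
#'   across parcels (with a random per-parcel gain). It emulates the
#'   trial-unspecific univariate response that dominates parcel-mean time
#'   series: across-voxel pattern correlations are exactly invariant to it,
#'   but time-series connectivity is not.
#' @param parcel_amp_sd sd of an independent per-(participant, parcel, trial)
#'   univariate amplitude fluctuation, likewise constant across a parcel's
#'   voxels. Pattern correlations are exactly invariant to it, while it
#'   degrades parcel-mean time-series connectivity -- which is what gives
#'   informational connectivity its edge over the conventional control
#'   analysis.
#' @param w2v_range range of the association-score sampler.
#' @param seed RNG seed; identical specs (incl. seed) give identical data.
#' @return an object of class `synthetic_spec`.
#' @seealso [simulate_dataset()], [planted_truth()]
#' @export
synthetic_spec <- function(n_participants = 31, n_trials = 144, n_runs = 3,
                           n_parcels = 100, voxels_per_parcel = 28,
                           planted_gradient = NULL,
                           s_lo = 3, s_hi = 7,
                           rank_base = 16, rank_weak = 18, rank_strong = 12,
                           modulated_parcels = NULL, coupling_parcels = NULL,
                           beta = 1.5,
                           noise_sd = 0.3, coef_noise_sd = 1,
                           run_effect_sd = 0.25, rating_noise_sd = 0.7,
                           global_amp_sd = 1, parcel_amp_sd = 1,
                           w2v_range = c(-0.05, 0.72), seed = 1L) {
  if (n_trials %% n_runs != 0) abort("n_trials must be a multiple of n_runs.")
  if (n_runs < 2) abort("at least 2 runs are required.")
  if (s_lo < 0 || s_hi < s_lo) abort("condition separation requires s_hi >= s_lo >= 0.")
  g <- planted_gradient %||% seq(-1, 1, length.out = n_parcels)
  if (length(g) != n_parcels || any(abs(g) > 1)) {
    abort("planted_gradient must give one value in [-1, 1] per parcel.")
  }
  # Default plants are graded along the transmodal half of the gradient
  # (profile max(g, 0)): the latent-rank condition difference and the
  # rating coupling both increase towards the apex, so dimensionality
  # contrast, semantic-brain alignment and the gradient co-vary over
  # parcels as in the mediation structure the pipeline estimates. Passing
  # explicit parcel sets switches to discrete plants of constant strength
  # (used for focused recovery experiments).
  gpos <- pmax(g, 0)
  rank_map <- matrix(rank_base, nrow = n_parcels, ncol = 3,
                     dimnames = list(NULL, c("weak", "middle", "strong")))
  if (is.null(modulated_parcels)) {
    rank_map[, "weak"] <- rank_base + round((rank_weak - rank_base) * gpos)
    rank_map[, "strong"] <- rank_base + round((rank_strong - rank_base) * gpos)
    modulated_parcels <- which(rank_map[, "weak"] != rank_map[, "strong"])
  } else {
    rank_map[modulated_parcels, "weak"] <- rank_weak
    rank_map[modulated_parcels, "strong"] <- rank_strong
  }
  if (is.null(coupling_parcels)) {
    beta_profile <- beta * gpos
    coupling_parcels <- which(beta_profile > 0)
  } else {
    beta_profile <- rep(0, n_parcels)
    beta_profile[coupling_parcels] <- beta
  }
  if (any(rank_map < 1)) abort("latent ranks must be >= 1.")
  if (max(rank_map) > voxels_per_parcel) {
    abort("infeasible rank: latent rank exceeds voxels_per_parcel.")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_trials = as.integer(n_trials), n_runs = as.integer(n_runs),
      n_parcels = as.integer(n_parcels),
      voxels_per_parcel = as.integer(voxels_per_parcel),
      planted_gradient = g, s_lo = s_lo, s_hi = s_hi,
      rank_map = rank_map,
      modulated_parcels = as.integer(modulated_parcels),
      coupling_parcels = as.integer(coupling_parcels),
      beta = beta, beta_profile = beta_profile,
      noise_sd = noise_sd, coef_noise_sd = coef_noise_sd,
      run_effect_sd = run_effect_sd, rating_noise_sd = rating_noise_sd,
      global_amp_sd = global_amp_sd, parcel_amp_sd = parcel_amp_sd,
      w2v_range = w2v_range, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Planted ground truth of a synthetic specification
#'
#' A deterministic function of the spec (independent of any noise
#' realisation): the latent gradient, the expected sign of the
#' strong-minus-weak gradient difference per parcel, the weak-minus-strong
#' latent rank difference, and the rating-coupling indicator.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `gradient`, `modulation_sign`, `rank_difference`,
#'   `coupling_indicator`, each of length `n_parcels`.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- spec$planted_gradient
  mod_sign <- if (spec$s_hi > spec$s_lo) sign(g - median(g)) else rep(0, length(g))
  list(
    gradient = g,
    modulation_sign = mod_sign,
    rank_difference = unname(spec$rank_map[, "weak"] - spec$rank_map[, "strong"]),
    coupling_indicator = as.integer(seq_along(g) %in% spec$coupling_parcels),
    coupling_profile = spec$beta_profile
  )
}

# Trial-level cross-parcel latent correlation: exponential decay with
# gradient distance at trial-specific rate m (a valid correlation matrix;
# the exponential kernel is positive definite on distinct points).
latent_covariance <- function(spec, m) {
  g <- spec$planted_gradient
  d <- abs(outer(g, g, "-"))
  exp(-m * d)
}

# Draw the shared latent trial coordinates: an n_trials x n_parcels x k_max
# array whose cross-parcel correlation at trial t is latent_covariance(m_t).
draw_latent_fields <- function(spec, m_per_trial, k_max) {
  p <- spec$n_parcels
  z <- array(0, dim = c(spec$n_trials, p, k_max))
  ms <- unique(m_per_trial)
  for (mv in ms) {
    l <- t(chol(latent_covariance(spec, mv)))
    for (t in which(m_per_trial == mv)) {
      z[t, , ] <- l %*% matrix(rnorm(p * k_max), p, k_max)
    }
  }
  z
}

#' Simulate a parcellated multi-participant dataset
#'
#' Generates trial-level multivoxel patterns for every participant (semantic
#' and chevron task windows), the behavioural table (word pairs, word2vec
#' scores, per-participant ratings and link descriptions), and the planted
#' truth, from a [synthetic_spec()]. The same seed always yields identical
#' output.
#'
#' @param spec a [synthetic_spec()].
#' @param atlas optional [parcellation_atlas()]; default
#'   [make_synthetic_atlas()] at the spec's size.
#' @param tasks which task windows to generate (`"semantic"`, `"chevron"`);
#'   dropping the chevron window roughly halves the cost for analyses that
#'   do not use the control task. The random draws for the semantic window
#'   are unaffected by the choice.
#' @return list with elements `patterns` (list of [trial_pattern_set()], one
#'   per participant, semantic window), `chevron_patterns` (same, chevron
#'   window), `behavior` (tibble: `trial_id`, `word_pair_1`, `word_pair_2`,
#'   `word2vec`), `ratings` (participants x trials integer matrix),
#'   `link_descriptions` (long tibble), `split` (tercile split), `truth`
#'   ([planted_truth()]), `atlas`, and `spec`.
#' @examples
#' sim <- simulate_dataset(synthetic_spec(
#'   n_participants = 4, n_trials = 12,
#'   n_parcels = 6, voxels_per_parcel = 8
#' ))
#' sim$patterns[[1]]
#' @export
simulate_dataset <- function(spec, atlas = NULL,
                             tasks = c("semantic", "chevron")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  atlas <- atlas %||% make_synthetic_atlas(spec$n_parcels, spec$voxels_per_parcel)
  if (n_parcels(atlas) != spec$n_parcels) {
    abort("atlas parcel count does not match the spec.")
  }
  np <- spec$n_participants
  nt <- spec$n_trials
  p <- spec$n_parcels
  v <- spec$voxels_per_parcel
  k_max <- max(spec$rank_map)
  set.seed(spec$seed)

  # --- stimuli and behaviour -------------------------------------------------
  w <- runif(nt, spec$w2v_range[1], spec$w2v_range[2])
  trial_ids <- sprintf("t%03d", seq_len(nt))
  run_labels <- rep(seq_len(spec$n_runs), each = nt / spec$n_runs)
  behavior <- tibble(
    trial_id = trial_ids,
    word_pair_1 = sprintf("noun%03da", seq_len(nt)),
    word_pair_2 = sprintf("noun%03db", seq_len(nt)),
    word2vec = w
  )
  split <- split_by_association(behavior)
  cond <- rep("middle", nt)
  cond[trial_ids %in% split$weak_ids] <- "weak"
  cond[trial_ids %in% split$strong_ids] <- "strong"

  w_norm <- (w - spec$w2v_range[1]) / diff(spec$w2v_range)
  ratings <- matrix(0L, np, nt)
  for (pp in seq_len(np)) {
    raw <- 4 * w_norm + rnorm(nt, sd = spec$rating_noise_sd)
    ratings[pp, ] <- as.integer(pmin(4, pmax(0, round(raw))))
  }
  # standardised ratings drive the planted coupling
  ratings_std <- t(apply(ratings, 1, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))

  # link descriptions: pool of candidate meanings shrinks with association
  # strength, so stronger pairs yield fewer unique meanings across the group
  pool_size <- pmax(1L, round(1 + (1 - w_norm) * 9))
  link_descriptions <- do.call(rbind, lapply(seq_len(nt), function(t) {
    cats <- sample(pool_size[t], np, replace = TRUE)
    data.frame(
      trial_id = trial_ids[t],
      participant_id = sprintf("p%02d", seq_len(np)),
      description = sprintf("meaning %s %d", trial_ids[t], cats)
    )
  }))

  # --- latent structure ------------------------------------------------------
  m_semantic <- spec$s_hi - (spec$s_hi - spec$s_lo) * w_norm
  m_chevron <- rep((spec$s_lo + spec$s_hi) / 2, nt)
  # round the decay rate to limit the number of Cholesky factorisations
  m_semantic <- round(m_semantic, 1)
  m_chevron <- round(m_chevron, 1)

  bases <- lapply(seq_len(p), function(i) {
    qr.Q(qr(matrix(rnorm(v * k_max), v, k_max)))
  })
  global_gain <- 1 + rnorm(p, sd = 0.2)
  coupling_dirs <- matrix(0, p, v)
  for (i in which(spec$beta_profile != 0)) {
    u <- rnorm(v)
    coupling_dirs[i, ] <- u / sqrt(sum(u^2))
  }
  z_sem <- draw_latent_fields(spec, m_semantic, k_max)
  z_chev <- if ("chevron" %in% tasks) {
    draw_latent_fields(spec, m_chevron, k_max)
  } else {
    NULL
  }

  rank_sem <- spec$rank_map[, cond, drop = FALSE] # p x nt
  rank_chev <- matrix(spec$rank_map[, "middle"], p, nt)

  make_patterns <- function(z, rank_by_trial, with_coupling) {
    lapply(seq_len(np), function(pp) {
      x <- matrix(0, nt, p * v)
      amp <- rnorm(nt, sd = spec$global_amp_sd)
      for (i in seq_len(p)) {
        # participant deviations are confined to the first k(condition)
        # components; the shared coordinates span all components so the
        # similarity structure carries no condition signature
        eta <- matrix(rnorm(nt * k_max, sd = spec$coef_noise_sd), nt, k_max)
        if (k_max > 1) {
          inactive <- outer(rank_by_trial[i, ], seq_len(k_max), function(k, l) l > k)
          eta[inactive] <- 0
        }
        c_mat <- matrix(z[, i, ], nt, k_max) + eta
        xi <- c_mat %*% t(bases[[i]])
        if (with_coupling && spec$beta_profile[i] != 0) {
          xi <- xi +
            spec$beta_profile[i] * outer(ratings_std[pp, ], coupling_dirs[i, ])
        }
        if (spec$run_effect_sd > 0) {
          for (r in seq_len(spec$n_runs)) {
            eff <- rnorm(v, sd = spec$run_effect_sd)
            rows <- which(run_labels == r)
            xi[rows, ] <- sweep(xi[rows, , drop = FALSE], 2L, eff, "+")
          }
        }
        if (spec$global_amp_sd > 0) {
          xi <- xi + global_gain[i] * amp %o% rep(1, v)
        }
        if (spec$parcel_amp_sd > 0) {
          xi <- xi + rnorm(nt, sd = spec$parcel_amp_sd) %o% rep(1, v)
        }
        xi <- xi + matrix(rnorm(nt * v, sd = spec$noise_sd), nt, v)
        x[, ((i - 1) * v + 1):(i * v)] <- xi
      }
      x
    })
  }

  sem_raw <- make_patterns(z_sem, rank_sem, with_coupling = TRUE)
  chev_raw <- if ("chevron" %in% tasks) {
    make_patterns(z_chev, rank_chev, with_coupling = FALSE)
  } else {
    NULL
  }

  v2p <- rep(seq_len(p), each = v)
  as_sets <- function(raw, window) {
    lapply(seq_len(np), function(pp) {
      trial_pattern_set(
        participant_id = sprintf("p%02d", pp),
        patterns = raw[[pp]],
        run_labels = run_labels,
        trial_ids = trial_ids,
        task_window = window,
        voxel_to_parcel = v2p
      )
    })
  }

  list(
    patterns = as_sets(sem_raw, "semantic"),
    chevron_patterns = if (is.null(chev_raw)) NULL else as_sets(chev_raw, "chevron"),
    behavior = behavior,
    ratings = ratings,
    link_descriptions = as_tibble(link_descriptions),
    split = split,
    condition = cond,
    truth = planted_truth(spec),
    atlas = atlas,
    spec = spec
  )
}
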