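#' Trial pattern set
#'
#' One participant's trial-level multivoxel activation patterns: one row per
#' trial (the unweighted average of the task-window volumes), one column per
#' voxel, with run labels and a voxel-to-parcel assignment. The task window
#' distinguishes the semantic decision period (TRs 4-6 after trial onset)
#' from the interleaved chevron control period (TRs 9-10).
#'
#' @param participant_id participant token.
#' @param patterns numeric matrix, trials x voxels; no non-finite values.
#' @param run_labels integer vector, run of each trial (>= 2 distinct runs).
#' @param trial_ids character/integer vector of trial identifiers, shared
#'   (same order) across participants.
#' @param task_window `"semantic"` or `"chevron"`.
#' @param voxel_to_parcel integer vector mapping each pattern column to a
#'   parcel id (see [voxel_to_parcel()]).
#' @return an object of class `trial_pattern_set`.
#' @export
trial_pattern_set <- function(participant_id, patterns, run_labels, trial_ids,
                              task_window = c("semantic", "chevron"),
                              voxel_to_parcel = NULL) {
  task_window <- match.arg(task_window)
  patterns <- as.matrix(patterns)
  if (any(!is.finite(patterns))) abort("patterns contain non-finite values.")
  if (nrow(patterns) != length(run_labels)) {
    abort("run_labels must have one entry per trial.")
  }
  if (nrow(patterns) != length(trial_ids)) {
    abort("trial_ids must have one entry per trial.")
  }
  if (length(unique(run_labels)) < 2) {
    abort("at least 2 runs are required (within-run pairs are excluded downstream).")
  }
  if (!is.null(voxel_to_parcel) && length(voxel_to_parcel) != ncol(patterns)) {
    abort("voxel_to_parcel must map every pattern column.")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      patterns = patterns,
      run_labels = as.integer(run_labels),
      trial_ids = trial_ids,
      task_window = task_window,
      voxel_to_parcel = voxel_to_parcel
    ),
    class = "trial_pattern_set"
  )
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat(
    "<trial_pattern_set> participant ", x$participant_id, ": ",
    nrow(x$patterns), " trials x ", ncol(x$patterns), " voxels, ",
    length(unique(x$run_labels)), " runs, window = ", x$task_window, "\n",
    sep = ""
  )
  invisible(x)
}

#' Extract trial patterns from a time series
#'
#' Averages, for each trial, the volumes at a fixed window of TR offsets
#' from trial onset. Offsets are 1-based: the window `4:6` means the 4th,
#' 5th, and 6th TR counting the onset TR as 1 (4.5-9 s after onset at a
#' 1.5 s TR) — the window used for the semantic decision; `9:10` picks out
#' the chevron control period (12-15 s after onset; with 13.5 s trials the
#' last chevron TR overlaps the next trial's fixation, which is accepted
#' and documented rather than truncated).
#'
#' @param time_series numeric matrix, TRs x voxels.
#' @param events data frame with columns `trial_id`, `onset_tr` (1-based TR
#'   index of trial onset) and `run`.
#' @param window_trs integer vector of 1-based TR offsets from onset.
#' @param voxel_to_parcel optional column-to-parcel map, stored on the result.
#' @param participant_id participant token.
#' @param task_window window label, `"semantic"` or `"chevron"`.
#' @return a [trial_pattern_set()], trials ordered as in `events`.
#' @examples
#' ts <- matrix(rnorm(20), nrow = 10, ncol = 2)
#' ev <- data.frame(trial_id = c("t1", "t2"), onset_tr = c(1, 6), run = c(1, 2))
#' extract_trial_patterns(ts, ev, window_trs = 1:2)
#' @export
extract_trial_patterns <- function(time_series, events, window_trs,
                                   voxel_to_parcel = NULL,
                                   participant_id = "p01",
                                   task_window = "semantic") {
  time_series <- as.matrix(time_series)
  if (any(window_trs < 1)) abort("window_trs are 1-based offsets (>= 1).")
  last_needed <- events$onset_tr + max(window_trs) - 1L
  bad <- which(last_needed > nrow(time_series))
  if (length(bad) > 0) {
    abort(paste0(
      "window exceeds the time series for trial(s): ",
      paste(events$trial_id[bad], collapse = ", ")
    ))
  }
  pat <- t(vapply(seq_len(nrow(events)), function(i) {
    rows <- events$onset_tr[i] + window_trs - 1L
    colMeans(time_series[rows, , drop = FALSE])
  }, numeric(ncol(time_series))))
  trial_pattern_set(
    participant_id = participant_id,
    patterns = pat,
    run_labels = events$run,
    trial_ids = events$trial_id,
    task_window = task_window,
    voxel_to_parcel = voxel_to_parcel
  )
}

#' Tercile split of trials by association strength
#'
#' Orders trials by ascending word2vec association score and returns the
#' bottom third (`weak`), middle, and top third (`strong`). Both extreme sets
#' have exactly `floor(n/3)` trials; when `n` is not divisible by 3 the
#' remainder goes to the middle tercile so the extreme sets stay balanced.
#' Ties in word2vec are broken by a stable sort on `trial_id`, so the split
#' is deterministic and seed-free.
#'
#' @param behavior data frame with columns `trial_id` and `word2vec`.
#' @return list with character/integer vectors `strong_ids`, `middle_ids`,
#'   `weak_ids` (disjoint; their union is all trials).
#' @examples
#' beh <- data.frame(trial_id = 1:6, word2vec = c(.1, .2, .3, .4, .5, .6))
#' split_by_association(beh)
#' @export
split_by_association <- function(behavior) {
  if (!all(c("trial_id", "word2vec") %in% names(behavior))) {
    abort("behavior must have columns trial_id and word2vec.")
  }
  if (any(is.na(behavior$word2vec))) abort("word2vec must be present for all trials.")
  n <- nrow(behavior)
  if (n < 3) abort("at least 3 trials are needed for a tercile split.")
  o <- order(behavior$word2vec, behavior$trial_id)
  ids <- behavior$trial_id[o]
  k <- floor(n / 3)
  list(
    strong_ids = ids[(n - k + 1):n],
    middle_ids = ids[(k + 1):(n - k)],
    weak_ids = ids[1:k]
  )
}

normalise_meaning <- function(x) {
  x <- gsub("[[:punct:][:space:]]+", " ", tolower(x))
  trimws(x)
}

#' Uniqueness of reported semantic links
#'
#' Counts, per trial, how many distinct meanings/links the participant group
#' produced, and expresses each reported category as the proportion of the
#' sample that gave it. Descriptions are compared by string equality after
#' lowercasing and stripping punctuation/extra whitespace; merging true
#' paraphrases into one meaning is the caller's responsibility (in the
#' original study this coding was done by hand).
#'
#' @param link_descriptions data frame with columns `trial_id`,
#'   `participant_id`, `description` (may contain `NA`/empty for no
#'   response).
#' @param n_participants total sample size for the proportion denominator
#'   (default: number of distinct participants in the table).
#' @return list with `trials` (tibble `trial_id`, `n_unique`), `responses`
#'   (tibble `trial_id`, `category`, `n_given`, `proportion`) and `warnings`
#'   (trial ids with no usable description; these get `n_unique = 0`).
#' @export
response_uniqueness <- function(link_descriptions, n_participants = NULL) {
  req <- c("trial_id", "participant_id", "description")
  if (!all(req %in% names(link_descriptions))) {
    abort("link_descriptions needs columns trial_id, participant_id, description.")
  }
  if (is.null(n_participants)) {
    n_participants <- length(unique(link_descriptions$participant_id))
  }
  df <- as_tibble(link_descriptions)
  df$category <- normalise_meaning(as.character(df$description))
  df$usable <- !is.na(df$description) & nzchar(trimws(df$category))
  responses <- df |>
    dplyr::filter(.data$usable) |>
    dplyr::distinct(.data$trial_id, .data$participant_id, .data$category) |>
    dplyr::count(.data$trial_id, .data$category, name = "n_given") |>
    dplyr::mutate(proportion = .data$n_given / n_participants)
  trials <- tibble(trial_id = unique(df$trial_id)) |>
    dplyr::left_join(
      dplyr::count(responses, .data$trial_id, name = "n_unique"),
      by = "trial_id"
    ) |>
    dplyr::mutate(n_unique = dplyr::coalesce(.data$n_unique, 0L))
  empties <- trials$trial_id[trials$n_unique == 0L]
  if (length(empties) > 0) {
    warn(paste0(
      "no usable link description for trial(s): ",
      paste(empties, collapse = ", "), " (count set to 0)."
    ))
  }
  list(trials = trials, responses = responses, warnings = empties)
}

#' Behavioural correlations with association strength
#'
#' Pearson correlations of (a) per-trial mean link-strength rating and (b)
#' per-trial unique-meaning count against word2vec scores.
#'
#' @param behavior data frame with `trial_id`, `word2vec` and either a
#'   `rating` column of per-trial means or participant-level `rating` rows
#'   (then means are taken per trial).
#' @param uniqueness optional `trials` tibble from [response_uniqueness()]
#'   (columns `trial_id`, `n_unique`).
#' @return tibble with one row per measure: `measure`, `r`, `p`, `n`.
#' @export
behavioral_correlations <- function(behavior, uniqueness = NULL) {
  mean_rating <- stats::aggregate(
    behavior$rating,
    by = list(trial_id = behavior$trial_id), FUN = mean
  )
  w2v <- behavior[!duplicated(behavior$trial_id), c("trial_id", "word2vec")]
  m <- merge(mean_rating, w2v, by = "trial_id")
  if (sd(m$x) == 0 || sd(m$word2vec) == 0) {
    abort("zero-variance input: cannot correlate ratings with word2vec.")
  }
  ct <- cor.test(m$x, m$word2vec)
  out <- tibble(
    measure = "rating_vs_word2vec",
    r = unname(ct$estimate), p = ct$p.value, n = nrow(m)
  )
  if (!is.null(uniqueness)) {
    mu <- merge(uniqueness, w2v, by = "trial_id")
    if (sd(mu$n_unique) == 0) {
      abort("zero-variance input: unique-meaning counts are constant.")
    }
    ct2 <- cor.test(mu$n_unique, mu$word2vec)
    out <- dplyr::bind_rows(out, tibble(
      measure = "meanings_vs_word2vec",
      r = unname(ct2$estimate), p = ct2$p.value, n = nrow(mu)
    ))
  }
  out
}
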