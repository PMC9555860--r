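# broom-style tidiers for the package's fitted objects.

#' Tidy a gradient set
#'
#' One row per parcel per component, with the score, the component index and
#' its variance ratio.
#'
#' @param x a `gradient_set`.
#' @param ... unused.
#' @return tibble: `parcel`, `component`, `score`, `variance_ratio`.
#' @export
tidy.gradient_set <- function(x, ...) {
  k <- ncol(x$scores)
  tidyr::expand_grid(
    component = seq_len(k),
    parcel = seq_len(nrow(x$scores))
  ) |>
    dplyr::mutate(
      score = purrr::map2_dbl(.data$parcel, .data$component, ~ x$scores[.x, .y]),
      variance_ratio = x$variance_ratio[.data$component]
    ) |>
    dplyr::arrange(.data$component, .data$parcel)
}

#' @rdname tidy.gradient_set
#' @export
glance.gradient_set <- function(x, ...) {
  tibble(
    n_parcels = nrow(x$scores),
    n_components = ncol(x$scores),
    variance_ratio_1 = x$variance_ratio[1],
    alignment = x$alignment,
    condition = x$condition
  )
}

#' Tidy a mediation result
#'
#' One row per path coefficient plus the indirect effect with its bootstrap
#' percentile interval.
#'
#' @param x a `mediation_result`.
#' @param ... unused.
#' @return tibble: `term`, `estimate`, `conf_low`, `conf_high`.
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble(
    term = c("a", "b", "c_prime", "c", "indirect"),
    estimate = unname(c(x$paths, x$indirect)),
    conf_low = c(rep(NA_real_, 4), x$ci_low),
    conf_high = c(rep(NA_real_, 4), x$ci_high)
  )
}

#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble(
    indirect = x$indirect,
    ci_low = x$ci_low, ci_high = x$ci_high,
    proportion_mediated = x$proportion_mediated,
    p_boot = x$p_boot, n = x$n, n_boot = x$n_boot
  )
}

#' Tidy a spin permutation test
#'
#' @param x a `spin_null`.
#' @param ... unused.
#' @return one-row tibble: `observed_r`, `p_spin`, `n_perm`, `null_mean`,
#'   `null_sd`.
#' @export
tidy.spin_null <- function(x, ...) {
  tibble(
    observed_r = x$observed_r, p_spin = x$p_spin, n_perm = x$n_perm,
    null_mean = mean(x$null_rs), null_sd = sd(x$null_rs)
  )
}
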