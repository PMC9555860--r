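# ggplot2 autoplot methods for the result types.

#' Plot gradient scores
#'
#' Scatter of parcel scores for one gradient component against parcel order,
#' coloured by network when an atlas is supplied.
#'
#' @param object a `gradient_set`.
#' @param component which gradient to show.
#' @param atlas optional [parcellation_atlas()] for network colours.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gradient_set <- function(object, component = 1, atlas = NULL, ...) {
  df <- tibble(
    parcel = seq_len(nrow(object$scores)),
    score = object$scores[, component],
    network = if (is.null(atlas)) "parcel" else atlas$network_labels
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parcel, y = .data$score,
                                   colour = .data$network)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      y = sprintf(
        "gradient %d score (%.1f%% variance)",
        component, 100 * object$variance_ratio[component]
      ),
      x = "parcel"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a spin-test null distribution
#'
#' Histogram of the rotation null with the observed correlation marked.
#'
#' @param object a `spin_null`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spin_null <- function(object, ...) {
  ggplot2::ggplot(tibble(r = object$null_rs), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_r, colour = "firebrick") +
    ggplot2::labs(
      x = "map correlation under rotation null",
      subtitle = sprintf("observed r = %.3f, p_spin = %.4g",
                         object$observed_r, object$p_spin)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mediation bootstrap distribution
#'
#' @param object a `mediation_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mediation_result <- function(object, ...) {
  ggplot2::ggplot(tibble(ab = object$boot_indirect), ggplot2::aes(x = .data$ab)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$indirect, colour = "firebrick") +
    ggplot2::geom_vline(
      xintercept = c(object$ci_low, object$ci_high),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "bootstrap indirect effect (a x b)") +
    ggplot2::theme_minimal()
}

#' Plot a dimensionality or alignment contrast map
#'
#' Per-parcel values with the FDR-significant parcels highlighted.
#'
#' @param data tibble from [dimensionality_contrast()] or
#'   [alignment_significance()].
#' @param value column to plot (default `difference`, falling back to `z`).
#' @return a ggplot.
#' @export
plot_contrast_map <- function(data, value = NULL) {
  vcol <- value %||% if ("difference" %in% names(data)) "difference" else "z"
  xcol <- if ("parcel" %in% names(data)) "parcel" else "location"
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[xcol]], y = .data[[vcol]],
    colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::theme_minimal()
}
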