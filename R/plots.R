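#' Plot a cohort records table
#'
#' Paired per-subject trajectories of the similarity index (or
#' non-overlapping volume) across timepoints, one panel per reference
#' plane.
#'
#' @param object An `asym_records` tibble from [run_cohort()].
#' @param quantity Column to plot: `"dice"` or `"nonoverlap_mm3"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asym_records
#' @export
autoplot.asym_records <- function(object, quantity = c("dice",
                                                       "nonoverlap_mm3"),
                                  ...) {
  quantity <- match.arg(quantity)
  lab <- if (quantity == "dice") {
    "similarity index"
  } else {
    expression("non-overlapping volume (" * mm^3 * ")")
  }
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$timepoint,
                               y = .data[[quantity]],
                               group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$reference_plane)) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Plot ramus/body distribution of the non-overlapping volume
#'
#' @param records An `asym_records` tibble from [run_cohort()].
#' @return A ggplot object: mean segment fractions per reference plane and
#'   timepoint.
#' @export
plot_segment_distribution <- function(records) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(records)[, c("reference_plane", "timepoint",
                                   "ramus_fraction", "body_fraction")],
    cols = c("ramus_fraction", "body_fraction"),
    names_to = "segment", values_to = "fraction")
  long$segment <- sub("_fraction", "", long$segment)
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$reference_plane, .data$timepoint,
                    .data$segment),
    fraction = mean(.data$fraction), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$timepoint,
                                     y = .data$fraction,
                                     fill = .data$segment)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$reference_plane)) +
    ggplot2::labs(x = NULL, y = "share of non-overlapping volume (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
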