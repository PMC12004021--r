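#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot risk intervals in the minimum/maximum risk plane
#'
#' Scatter of (minimum risk, maximum risk) pairs over the category regions:
#' the diagonal is the ideal fully observed case (an exact risk value), the
#' region below the low cutoff on both axes is low risk, the region with
#' minimum risk at or above the high cutoff is high risk, and intervals
#' spanning both cutoffs fall in the not-specified region.
#'
#' @param data Data frame with columns `risk_min` and `risk_max` (e.g. from
#'   [cohort_risk()] or the `best` table of a report).
#' @param cutoffs Named numeric `c(low, high)`.
#' @return A ggplot object.
#' @export
plot_risk_plane <- function(data, cutoffs = c(low = 0.05, high = 0.10)) {
  data <- as_tibble(data) |>
    filter(!is.na(.data$risk_min), !is.na(.data$risk_max)) |>
    mutate(category = categorize_risk(.data$risk_min, .data$risk_max, cutoffs))
  ggplot2::ggplot(data, ggplot2::aes(.data$risk_min, .data$risk_max)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = cutoffs, colour = "grey70") +
    ggplot2::geom_hline(yintercept = cutoffs, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category), alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      low = "#1b9e77", moderate = "#e6ab02", high = "#d95f02",
      not_specified = "grey40"), drop = FALSE) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "minimum 10-year risk", y = "maximum 10-year risk",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Plot per-year mean risk difference for one or more runs
#'
#' Line plot of the average risk-interval width by grid year, optionally
#' comparing several configurations (e.g. the nested enrichment iterations).
#'
#' @param by_year A tibble from [mean_risk_difference_by_year()], or a named
#'   list of them (names become the legend).
#' @return A ggplot object.
#' @export
plot_risk_difference <- function(by_year) {
  if (!is.data.frame(by_year)) {
    by_year <- purrr::imap(by_year, \(df, nm) mutate(df, run = nm)) |> bind_rows()
  } else if (!"run" %in% names(by_year)) {
    by_year <- mutate(by_year, run = "run")
  }
  ggplot2::ggplot(by_year,
                  ggplot2::aes(.data$year, .data$mean_width,
                               colour = .data$run, group = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = "year", y = "mean risk difference (max - min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort report
#'
#' @param object A `clivd_report`.
#' @param type `"by_year"` (mean risk difference trajectory) or `"plane"`
#'   (best per-patient intervals in the min/max risk plane).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clivd_report <- function(object, type = c("by_year", "plane"), ...) {
  type <- match.arg(type)
  if (type == "by_year") {
    plot_risk_difference(object$by_year)
  } else {
    plot_risk_plane(object$best, object$config$cutoffs)
  }
}
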