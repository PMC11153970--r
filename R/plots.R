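#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an implementation result
#'
#' Two views of the daily implementation record:
#'
#' * `type = "calendar"` — a monitor-by-day tile calendar coloured optimal /
#'   suboptimal / nonmonitored, the natural way to eyeball censoring and
#'   Off-cycle structure;
#' * `type = "rates"` — per-patient implementation rates as a dot plot.
#'
#' @param object An `adh_implementation` object.
#' @param type `"calendar"` or `"rates"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adh_implementation
#' @export
autoplot.adh_implementation <- function(object, type = c("calendar", "rates"),
                                        ...) {
  type <- match.arg(type)
  if (!object$ok) stop("pipeline blocked by critical errors; nothing to plot",
                       call. = FALSE)
  if (type == "calendar") plot_implementation_calendar(object)
  else plot_implementation_rates(object)
}

#' @rdname autoplot.adh_implementation
#' @param result An `adh_implementation` object.
#' @export
plot_implementation_calendar <- function(result) {
  df <- result$monitor_daily |>
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(.data$implementation) ~ "nonmonitored",
        .data$implementation == 1L ~ "optimal",
        TRUE ~ "suboptimal"
      ),
      em = paste(.data$patient_code, .data$monitor, sep = " / ")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$em,
                                   fill = .data$status)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(optimal = "#2b8cbe",
                                          suboptimal = "#e34a33",
                                          nonmonitored = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "implementation",
                  title = "Daily implementation by electronic monitor") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.adh_implementation
#' @export
plot_implementation_rates <- function(result) {
  df <- result$patient_summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$implementation_rate,
                                   y = stats::reorder(.data$patient_code,
                                                      .data$implementation_rate))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "implementation rate (optimal / monitored days)",
                  y = NULL, title = "Implementation by patient") +
    ggplot2::theme_minimal()
}
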