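#' Plot a simulated voltage trace
#'
#' @param object A `fiber_sim` from [simulate_fiber()].
#' @param ... Unused.
#' @return A ggplot: voltage against time, one panel per recorded
#'   compartment, detected spikes marked at the recording point.
#' @export
autoplot.fiber_sim <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$time_ms, y = .data$v_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::mutate(object$spikes,
                                             compartment = "recording",
                                             v_mv = 0),
                        ggplot2::aes(x = .data$t_ms, y = .data$v_mv),
                        color = "red", shape = 4) +
    ggplot2::facet_wrap(~compartment, ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  title = object$fiber)
}

#' Raster plot of a whole-nerve simulation
#'
#' @param object A `nerve_sim` from [simulate_nerve()].
#' @param ... Unused.
#' @return A ggplot raster of spike times per fiber.
#' @export
autoplot.nerve_sim <- function(object, ...) {
  ggplot2::ggplot(object$merged,
                  ggplot2::aes(x = .data$t_ms / 1000, y = .data$fiber_id)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot simulated clamp curves against their Boltzmann references
#'
#' @param curves One clamp-curve tibble or a row-bound set (as returned by
#'   [simulate_activation_curve()] / [simulate_inactivation_curve()]).
#' @return A ggplot of normalized value against voltage, colored by channel
#'   and faceted by protocol.
#' @export
plot_clamp_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$voltage_mv,
                                       y = .data$normalized_value,
                                       color = .data$channel_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~protocol) +
    ggplot2::labs(x = "voltage (mV)", y = "normalized value", color = NULL)
}

#' Plot an ISI distribution
#'
#' @param isi An [interspike_intervals()] tibble (or several row-bound, with a
#'   grouping column `source`).
#' @param binwidth_s Histogram bin width (s).
#' @return A ggplot histogram of inter-spike intervals.
#' @export
plot_isi_distribution <- function(isi, binwidth_s = 0.02) {
  p <- ggplot2::ggplot(isi, ggplot2::aes(x = .data$isi_s))
  if ("source" %in% names(isi)) {
    p <- p + ggplot2::aes(fill = .data$source)
  }
  p + ggplot2::geom_histogram(binwidth = binwidth_s, position = "identity",
                              alpha = 0.6) +
    ggplot2::labs(x = "inter-spike interval (s)", y = "count")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fiber simulation into its spike table
#' @param x A `fiber_sim` object.
#' @param ... Unused.
#' @return The spike tibble (`fiber_id`, `t_ms`).
#' @method tidy fiber_sim
#' @export
tidy.fiber_sim <- function(x, ...) x$spikes

#' One-row summary of a fiber simulation
#' @param x A `fiber_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: fiber label, duration, spike count, mean rate.
#' @method glance fiber_sim
#' @export
glance.fiber_sim <- function(x, ...) {
  dplyr::mutate(firing_summary(x$spikes, c(0, x$duration_ms)),
                fiber = x$fiber, duration_ms = x$duration_ms)
}

#' @method tidy nerve_sim
#' @export
tidy.nerve_sim <- function(x, ...) x$merged

#' @method glance nerve_sim
#' @export
glance.nerve_sim <- function(x, ...) {
  dplyr::mutate(firing_summary(x$merged, c(0, x$duration_ms)),
                n_fibers = length(x$per_fiber))
}
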