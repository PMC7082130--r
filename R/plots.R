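# ggplot2 display helpers.

#' Plot a state-space density map
#'
#' Filled density raster with optional contour lines at the standard low
#' and high display thresholds (see [contour_levels()]).
#'
#' @param object A `state_space_map`.
#' @param contours Draw the 2.5x/5x baseline contour lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_space_map <- function(object, contours = TRUE, ...) {
  d <- tidy.state_space_map(object)
  n_sub <- attr(object, "n_subjects") %||% 1L
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ssr1, y = .data$ssr2,
                                       fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::labs(x = "SSR1 (6.5-9 / 0.5-9 Hz)",
                  y = "SSR2 (0.5-20 / 0.5-100 Hz)") +
    ggplot2::theme_minimal()
  if (contours) {
    lev <- contour_levels(n_sub, nrow(object))
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = .data$weight), breaks = unname(lev),
      colour = "white", linewidth = 0.3)
  }
  p
}

#' Plot detected spindle events over time
#'
#' One horizontal segment per event, by channel, colored by acceptance.
#'
#' @param object A `spindle_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spindle_events <- function(object, ...) {
  d <- tidy.spindle_events(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start, xend = .data$end,
                                  y = .data$channel, yend = .data$channel,
                                  colour = .data$accepted)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "accepted") +
    ggplot2::theme_minimal()
}

#' Plot a connectivity matrix
#'
#' Heatmap of pairwise or global simultaneous-spindle connectivity.
#'
#' @param conn A `spindle_connectivity` tibble.
#' @param value `"weight"` or `"count"`.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(conn, value = c("weight", "count")) {
  value <- match.arg(value)
  ggplot2::ggplot(conn, ggplot2::aes(x = .data$channel_a,
                                     y = .data$channel_b,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a within-cycle spindle density profile
#'
#' @param profile Output of [cycle_density_profile()].
#' @return A ggplot object.
#' @export
plot_cycle_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$period,
                                        y = .data$proportion,
                                        colour = factor(.data$cycle))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "3 min period within cycle",
                  y = "proportion of spindles", colour = "cycle") +
    ggplot2::theme_minimal()
}

#' Plot a few seconds of a recording
#'
#' Stacked channel traces, optionally with detected events shaded.
#'
#' @param rec A recording.
#' @param from,to Time window in seconds.
#' @param events Optional `spindle_events` to overlay.
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, from = 0, to = 30, events = NULL) {
  seg <- slice_recording(rec, from, to)
  d <- tidyr::pivot_longer(tibble::as_tibble(seg), -"time",
                           names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- tibble::as_tibble(events)
    ev <- ev[ev$start < to & ev$end > from, , drop = FALSE]
    if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
    if (nrow(ev) > 0L) {
      p <- p + ggplot2::geom_rect(
        data = ev, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf),
        fill = "orange", alpha = 0.3)
    }
  }
  p
}
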