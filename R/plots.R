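# ggplot2 visualisations for the main result types.

#' Plot a stimulus layout
#'
#' Elements at their visual-angle positions (white/black polarity), the
#' virtual shape contour, and the 8-deg stimulus area.
#'
#' @param object A `stimulus_layout`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stimulus_layout <- function(object, ...) {
  sh <- attr(object, "shape")
  verts <- polygon_vertices(sh)
  verts <- dplyr::bind_rows(verts, verts[1, ])
  circ <- tibble::tibble(a = seq(0, 2 * pi, length.out = 181),
                         x_deg = 4 * cos(a), y_deg = 4 * sin(a))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_deg, y = .data$y_deg)) +
    ggplot2::geom_path(data = circ, linetype = 3, colour = "grey60") +
    ggplot2::geom_path(data = verts, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$polarity), shape = 21,
                        size = 4, colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(white = "white", black = "black")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a TANOVA p-value trace with significant windows shaded
#'
#' @param object A `tanova_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tanova_result <- function(object, ...) {
  w <- attr(object, "windows")
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$time_ms, y = .data$p)) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ms)", y = "randomization p") +
    ggplot2::theme_minimal()
  if (nrow(w) > 0)
    p <- p + ggplot2::geom_rect(
      data = w, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = 0, ymax = Inf),
      fill = "steelblue", alpha = 0.2)
  p
}

#' Plot the cross-validation criterion across candidate map counts
#'
#' @param object A `microstate_segmentation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microstate_segmentation <- function(object, ...) {
  ggplot2::ggplot(object$criteria, ggplot2::aes(x = .data$q, y = .data$cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$q_star, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "number of microstate maps", y = "CV criterion") +
    ggplot2::theme_minimal()
}

#' Butterfly plot of an ERP with its global field power
#'
#' @param erp A `subject_erp`.
#' @return A ggplot: one line per channel plus the GFP trace.
#' @export
plot_butterfly <- function(erp) {
  d <- tibble::as_tibble(t(erp$data), .name_repair = "minimal")
  names(d) <- rownames(erp$data)
  d$time_ms <- erp$times_ms
  long <- tidyr::pivot_longer(d, -"time_ms", names_to = "channel",
                              values_to = "uV")
  g <- tibble::tibble(time_ms = erp$times_ms, uV = gfp(erp$data))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$uV,
                                     group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.2) +
    ggplot2::geom_line(data = g, inherit.aes = FALSE, linewidth = 0.9,
                       colour = "firebrick",
                       ggplot2::aes(x = .data$time_ms, y = .data$uV)) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)",
                  subtitle = "channels (grey) and GFP (red)") +
    ggplot2::theme_minimal()
}

#' Behavioural cell means plot
#'
#' Accuracy and mean RT as a function of numerosity, split by the second
#' design factor.
#'
#' @param stats A `behavior_stats` object.
#' @return A ggplot.
#' @export
plot_behavior <- function(stats) {
  cells <- stats$cells
  fac2 <- setdiff(names(cells), c("subject", "n_elements", "accuracy", "rt_ms"))[1]
  long <- cells |>
    tidyr::pivot_longer(c("accuracy", "rt_ms"), names_to = "measure") |>
    dplyr::group_by(.data$n_elements, .data[[fac2]], .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_elements, y = .data$mean,
                                     colour = .data[[fac2]])) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = "number of elements", y = NULL) +
    ggplot2::theme_minimal()
}
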