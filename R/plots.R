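## ggplot2 views of the main result objects.

#' Plot a trajectory with spike locations
#'
#' @param traj A `gt_trajectory`.
#' @param spikes Optional spike times whose positions are overlaid.
#' @return A ggplot.
#' @export
plot_trajectory <- function(traj, spikes = NULL) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$x1, y = .data$y1)) +
    ggplot2::geom_path(colour = "grey60", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(spikes) && length(spikes) > 0) {
    sx <- approx(traj$t, traj$x1, xout = spikes, rule = 2)$y
    sy <- approx(traj$t, traj$y1, xout = spikes, rule = 2)$y
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(x1 = sx, y1 = sy),
      colour = "red", size = 0.5)
  }
  p
}

ratemap_long <- function(map, value = "rate") {
  g <- expand.grid(x = map$x, y = map$y)
  g$value <- as.vector(map[[value]])
  tibble::as_tibble(g)
}

#' @rdname autoplot.gt_ratemap
#' @param object,x A `gt_ratemap` or `gt_acorr2d`.
#' @param ... Unused.
#' @export
autoplot.gt_ratemap <- function(object, ...) {
  ggplot2::ggplot(ratemap_long(object),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "Hz") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("peak %.1f Hz", object$peak_rate),
                  x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Plot methods for maps, correlograms and profiles
#'
#' `autoplot()` methods render rate maps, 2D autocorrelograms, linearized
#' profiles and 1D autocorrelations (with their Toeplitz rendering
#' available through [plot_toeplitz()]).
#'
#' @name autoplot.gt_ratemap
#' @export
autoplot.gt_acorr2d <- function(object, ...) {
  g <- expand.grid(x = object$lag_x, y = object$lag_y)
  g$value <- as.vector(object$r)
  ggplot2::ggplot(tibble::as_tibble(g),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "r") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lag x (cm)", y = "lag y (cm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gt_ratemap
#' @export
autoplot.gt_linear_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid, .data$rate)) +
    ggplot2::geom_col(width = attr(object, "bin"), fill = "grey30") +
    ggplot2::labs(x = sprintf("%s (%s)", attr(object, "frame"),
                              if (attr(object, "frame") == "time") "s" else "cm"),
                  y = "rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gt_ratemap
#' @export
autoplot.gt_acorr1d <- function(object, ...) {
  pk <- tibble::tibble(lag = attr(object, "peak_lags"),
                       r = attr(object, "peak_values"))
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "red") +
    ggplot2::labs(x = "lag", y = "autocorrelation") +
    ggplot2::theme_minimal()
}

#' Toeplitz rendering of a 1D autocorrelation
#'
#' @param acorr A `gt_acorr1d`.
#' @param extent Extent in frame units (default 500).
#' @return A ggplot.
#' @export
plot_toeplitz <- function(acorr, extent = 500) {
  m <- toeplitz_rendering(acorr, extent)
  binw <- attr(acorr, "bin")
  g <- expand.grid(a = (seq_len(nrow(m)) - 1) * binw,
                   b = (seq_len(ncol(m)) - 1) * binw)
  g$value <- as.vector(m)
  ggplot2::ggplot(tibble::as_tibble(g),
                  ggplot2::aes(.data$a, .data$b, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "r") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "position (frame units)", y = "position (frame units)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gt_ratemap
#' @export
autoplot.gt_hd_tuning <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$direction, .data$rate)) +
    ggplot2::geom_col(width = 6, fill = "grey30") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::labs(x = NULL, y = "rate (Hz)",
                  title = sprintf("RVL %.2f, PFD %.0f deg",
                                  object$vector_length, object$pfd)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gt_ratemap
#' @export
autoplot.gt_speed_tuning <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$speed, .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "red") +
    ggplot2::labs(x = "speed (cm/s)", y = "rate (Hz)",
                  title = sprintf("r = %.2f, slope %.3f Hz/(cm/s)",
                                  object$r, object$slope)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gt_ratemap
#' @export
autoplot.gt_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (cycles/cm)", y = "power") +
    ggplot2::theme_minimal()
}

#' Plot a lap-position matrix
#'
#' @param lapmat A `gt_lap_matrix`.
#' @return A ggplot of rate by track position and lap.
#' @export
plot_lap_matrix <- function(lapmat) {
  binw <- attr(lapmat, "bin")
  g <- expand.grid(lap = seq_len(nrow(lapmat)),
                   pos = (seq_len(ncol(lapmat)) - 0.5) * binw)
  g$rate <- as.vector(lapmat)
  ggplot2::ggplot(tibble::as_tibble(g),
                  ggplot2::aes(.data$pos, .data$lap, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "Hz") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "track position (cm)", y = "lap") +
    ggplot2::theme_minimal()
}
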