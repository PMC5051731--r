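#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.msd_drift_fit <- function(x, ...) {
  tibble::tibble(term = c("d_eff", "v_eff"),
                 estimate = c(x$d_eff, x$v_eff),
                 unit = c("um^2/s", "um/s"))
}

#' @export
glance.msd_drift_fit <- function(x, ...) {
  tibble::tibble(d_eff = x$d_eff, v_eff = x$v_eff,
                 residual = x$residual, n_lags = x$n_lags)
}

#' @export
tidy.msd_anom_fit <- function(x, ...) {
  tibble::tibble(term = c("d_prime", "alpha"),
                 estimate = c(x$d_prime, x$alpha),
                 unit = c("um^2/s^alpha", ""))
}

#' @export
glance.msd_anom_fit <- function(x, ...) {
  tibble::tibble(d_prime = x$d_prime, alpha = x$alpha,
                 residual = x$residual, n_lags = x$n_lags)
}

#' @export
tidy.distance_time_fit <- function(x, ...) {
  tibble::tibble(term = c("d_max", "t_half", "n"),
                 estimate = c(x$d_max, x$t_half, x$n),
                 unit = c("um", "s", ""))
}

#' @export
glance.distance_time_fit <- function(x, ...) {
  tibble::tibble(d_max = x$d_max, t_half = x$t_half, n = x$n,
                 r_squared = x$r_squared, mode = x$mode,
                 reliable = x$reliable)
}

#' @export
tidy.rank_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.rank_result <- function(x, ...) {
  b <- attr(x, "best")
  tibble::tibble(n_sets = nrow(x), best_k = b$k,
                 a_rhalf = b$a_rhalf, a_s = b$a_s,
                 r_rhalf = b$r_rhalf, r_s = b$r_s,
                 sum_rank = b$sum_rank)
}

#' @export
glance.aster_run <- function(x, ...) {
  v <- instantaneous_velocities(x$tracks)
  tibble::tibble(scenario = x$config$scenario,
                 n_mtoc = x$config$n_mtoc, n_mt = x$config$n_mt,
                 f_0 = x$config$f_0,
                 capture_fraction = x$capture_fraction,
                 mean_v = mean(v$v_um_s),
                 mean_filament_length = mean(x$mean_filament_length$length_um))
}

#' Plot trajectories, coloured by track
#'
#' @param object An `aster_tracks` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aster_tracks <- function(object, ...) {
  r_cell <- attr(object, "r_cell") %||% 40
  r_chr <- attr(object, "r_chr") %||% 10
  circ <- function(r) tibble::tibble(th = seq(0, 2 * pi, length.out = 181),
                                     x_um = r * cos(.data$th),
                                     y_um = r * sin(.data$th))
  ggplot2::ggplot(object, ggplot2::aes(.data$x_um, .data$y_um,
                                       group = .data$track_id,
                                       colour = factor(.data$track_id))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_path(data = circ(r_cell), inherit.aes = FALSE,
                       ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_path(data = circ(r_chr), inherit.aes = FALSE,
                       ggplot2::aes(.data$x_um, .data$y_um), linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot an msd curve, optionally with a drift-diffusion fit
#'
#' @param curve A tibble with `lag_s`, `msd_um2`.
#' @param fit Optional `msd_drift_fit`.
#' @return A ggplot.
#' @export
plot_msd <- function(curve, fit = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$lag_s, .data$msd_um2)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag (s)", y = "msd (um^2)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(lag_s = seq(min(curve$lag_s), max(curve$lag_s),
                                       length.out = 200))
    grid$msd_um2 <- 4 * fit$d_eff * grid$lag_s + (fit$v_eff * grid$lag_s)^2
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}

#' Plot a radial profile with mean and s.d. ribbon
#'
#' @param profile Output of [radial_profile()].
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_radial_profile <- function(profile, ylab = "chi") {
  ggplot2::ggplot(profile, ggplot2::aes(.data$r_mid, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "radial distance (um)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot drift-field profiles across the cell
#'
#' @param attract,repel [drift_field()]s.
#' @param r_cell,r_chr Geometry (um).
#' @return A ggplot of both weights against radial distance from the centre.
#' @export
plot_drift_field <- function(attract, repel = NULL, r_cell = 40, r_chr = 10) {
  r <- seq(r_chr, r_cell, length.out = 200)
  dat <- tibble::tibble(r = r, weight = field_weight(attract, r - r_chr),
                        field = "attractive")
  if (!is.null(repel)) {
    dat <- dplyr::bind_rows(dat, tibble::tibble(
      r = r, weight = field_weight(repel, r_cell - r), field = "repulsive"))
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$r, .data$weight,
                                    colour = .data$field)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radial distance from centre (um)", y = "field weight") +
    ggplot2::theme_minimal()
}
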