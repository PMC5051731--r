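#' Down-sample trajectories to a coarser frame interval
#'
#' Emulates the sparse sampling of time-lapse experiments: for each track,
#' the samples nearest to multiples of `interval` (counted from the first
#' sample) are kept; the first and last samples are always preserved.
#'
#' @param tracks A trajectory tibble (`track_id`, `t_s`, `x_um`, `y_um`).
#' @param interval Target frame interval (s); must be at least the native
#'   sampling step.
#' @return A trajectory tibble with the same columns and attributes.
#' @export
downsample_tracks <- function(tracks, interval) {
  check_tracks(tracks)
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    abort("`interval` must be a positive number", class = "asterdrift_invalid_interval")
  }
  native <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(step = if (dplyr::n() > 1) min(diff(.data$t_s)) else NA_real_,
                     .groups = "drop")
  min_step <- suppressWarnings(min(native$step, na.rm = TRUE))
  if (is.finite(min_step) && interval < min_step - 1e-9) {
    abort("`interval` is shorter than the native sampling step",
          class = "asterdrift_invalid_interval")
  }
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n <= 2) return(df)
      targets <- seq(df$t_s[1], df$t_s[n], by = interval)
      idx <- vapply(targets, function(tt) which.min(abs(df$t_s - tt)), integer(1))
      idx <- sort(unique(c(idx, 1L, n)))
      df[idx, ]
    }) |>
    dplyr::ungroup()
  as_aster_tracks(out, r_cell = attr(tracks, "r_cell") %||% 40,
                  r_chr = attr(tracks, "r_chr") %||% 10)
}

#' Instantaneous velocities of tracked particles
#'
#' Per consecutive sample pair, the Euclidean displacement divided by the
#' time gap (`v = dL/dt`).
#'
#' @inheritParams downsample_tracks
#' @return A tibble with `track_id`, `t_s` (end of the step) and `v_um_s`.
#' @export
instantaneous_velocities <- function(tracks) {
  check_tracks(tracks)
  ns <- dplyr::count(tracks, .data$track_id)
  if (any(ns$n < 2)) {
    abort("every track needs at least 2 samples",
          class = "asterdrift_insufficient_data")
  }
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(v_um_s = c(NA_real_,
                             sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) /
                               diff(.data$t_s))) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$v_um_s)) |>
    dplyr::select("track_id", "t_s", "v_um_s")
}

#' Directionality (tortuosity) of each track
#'
#' `chi = d_net / L`: the net end-to-end displacement over the summed path
#' length. `chi = 1` is perfectly directed motion; values near 0 indicate a
#' tortuous, random path. Zero-length paths give `NA` (excluded from binned
#' profiles).
#'
#' @inheritParams downsample_tracks
#' @return A tibble with `track_id` and `chi` in `[0, 1]` (or `NA`).
#' @export
track_directionality <- function(tracks) {
  check_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      chi = {
        if (dplyr::n() < 2) NA_real_ else {
          L <- sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2))
          d_net <- sqrt((.data$x_um[dplyr::n()] - .data$x_um[1])^2 +
                        (.data$y_um[dplyr::n()] - .data$y_um[1])^2)
          if (L > 0) d_net / L else NA_real_
        }
      },
      .groups = "drop")
}

#' Per-track summary of motility measures
#'
#' @inheritParams downsample_tracks
#' @param r_chr Chromatin radius (um); defaults to the tracks attribute.
#' @return A tibble with one row per track: `d_n` (nucleation distance from
#'   the chromatin edge, um), `t_c` (capture time, s; `NA` if the track never
#'   enters the chromatin disk), `chi`, `mean_v` (um/s), `n_samples`,
#'   `duration`.
#' @export
track_summary <- function(tracks, r_chr = NULL) {
  check_tracks(tracks)
  r_chr <- r_chr %||% attr(tracks, "r_chr") %||% 10
  chi <- track_directionality(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      duration = .data$t_s[dplyr::n()] - .data$t_s[1],
      d_n = max(0, sqrt(.data$x_um[1]^2 + .data$y_um[1]^2) - r_chr),
      r_start = sqrt(.data$x_um[1]^2 + .data$y_um[1]^2),
      t_c = {
        r <- sqrt(.data$x_um^2 + .data$y_um^2)
        hit <- which(r <= r_chr)
        if (length(hit)) .data$t_s[hit[1]] else NA_real_
      },
      mean_v = if (dplyr::n() > 1) {
        mean(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) / diff(.data$t_s))
      } else NA_real_,
      .groups = "drop") |>
    dplyr::left_join(chi, by = "track_id")
}

#' Mean squared displacement of each track
#'
#' For each lag (integer multiples of the track's sampling interval, up to
#' 3/4 of the track duration) the squared displacement is averaged over all
#' start points (overlapping windows):
#' \deqn{\langle \Delta r^2 \rangle(\delta t) =
#'   \langle |r(t + \delta t) - r(t)|^2 \rangle_t}
#' The 3/4-duration cut-off avoids the poorly averaged long-lag tail.
#'
#' Tracks with fewer than 3 samples (e.g. captured within two frames) carry
#' no lag information and are dropped; an error is raised only if no track
#' remains.
#'
#' @inheritParams downsample_tracks
#' @param max_lag_frac Largest lag as a fraction of track duration.
#' @return A tibble with `track_id`, `lag_s`, `msd_um2`, `n_pairs`.
#' @export
track_msd <- function(tracks, max_lag_frac = 0.75) {
  check_tracks(tracks)
  ns <- dplyr::count(tracks, .data$track_id)
  if (all(ns$n < 3)) {
    abort("need at least one track with 3 or more samples",
          class = "asterdrift_insufficient_data")
  }
  # tracks too short for any lag (e.g. captured within two frames) are dropped
  keep <- ns$track_id[ns$n >= 3]
  tracks <- dplyr::filter(tracks, .data$track_id %in% keep)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      dt_s <- mean(diff(df$t_s))
      duration <- df$t_s[n] - df$t_s[1]
      k_max <- min(n - 1L, floor(max_lag_frac * duration / dt_s))
      if (k_max < 1L) return(tibble::tibble(lag_s = numeric(0),
                                            msd_um2 = numeric(0),
                                            n_pairs = integer(0)))
      purrr::map_dfr(seq_len(k_max), function(k) {
        i <- seq_len(n - k)
        d2 <- (df$x_um[i + k] - df$x_um[i])^2 + (df$y_um[i + k] - df$y_um[i])^2
        tibble::tibble(lag_s = k * dt_s, msd_um2 = mean(d2),
                       n_pairs = length(i))
      })
    }) |>
    dplyr::ungroup()
}

#' Ensemble mean squared displacement
#'
#' Pools the per-track msd over all tracks, weighting each track's value at
#' a lag by its number of displacement pairs. Lags are grouped on a common
#' grid (rounded to the typical sampling interval), so tracks should share a
#' sampling interval (e.g. after [downsample_tracks()]).
#'
#' @inheritParams track_msd
#' @return A tibble with `lag_s`, `msd_um2`, `n_pairs` (summed).
#' @export
ensemble_msd <- function(tracks, max_lag_frac = 0.75) {
  per <- track_msd(tracks, max_lag_frac = max_lag_frac)
  if (nrow(per) == 0) return(tibble::tibble(lag_s = numeric(0),
                                            msd_um2 = numeric(0),
                                            n_pairs = integer(0)))
  base_dt <- min(per$lag_s)
  per |>
    dplyr::mutate(lag_k = round(.data$lag_s / base_dt)) |>
    dplyr::group_by(.data$lag_k) |>
    dplyr::summarise(
      lag_s = sum(.data$lag_s * .data$n_pairs) / sum(.data$n_pairs),
      msd_um2 = sum(.data$msd_um2 * .data$n_pairs) / sum(.data$n_pairs),
      n_pairs = sum(.data$n_pairs), .groups = "drop") |>
    dplyr::select(-"lag_k")
}

#' Radial profile of directionality or speed
#'
#' Bins a motility measure by radial distance from the cell centre. For
#' `measure = "chi"` each track contributes its whole-track directionality,
#' assigned to the bin of its nucleation (first-sample) radius; for
#' `measure = "v"` each step contributes its instantaneous speed, assigned to
#' the bin of the step's starting radius. Empty bins are absent from the
#' output.
#'
#' With `chi_window = NULL` (default) each track contributes one whole-track
#' chi value; with an integer window size, chi is instead computed over
#' sliding windows of that many frames and each window is assigned to the
#' bin of its starting radius. The windowed variant resolves the local
#' directionality structure (directed at the cortex and near chromatin,
#' random in the mid-zone) that whole-track values blur out.
#'
#' @inheritParams downsample_tracks
#' @param r_cell Cell radius (um); defaults to the tracks attribute.
#' @param bin_width Radial bin width (um).
#' @param measure `"chi"` or `"v"`.
#' @param chi_window Optional window length (frames) for windowed chi.
#' @return A tibble with `r_lo`, `r_hi`, `r_mid`, `mean`, `sd`, `n`.
#' @export
radial_profile <- function(tracks, r_cell = NULL, bin_width = 5,
                           measure = c("chi", "v"), chi_window = NULL) {
  check_tracks(tracks)
  measure <- match.arg(measure)
  if (bin_width <= 0) abort("`bin_width` must be positive",
                            class = "asterdrift_invalid_interval")
  r_cell <- r_cell %||% attr(tracks, "r_cell") %||% 40
  breaks <- seq(0, r_cell + bin_width, by = bin_width)
  if (measure == "chi" && !is.null(chi_window)) {
    w <- as.integer(chi_window)
    if (w < 2) abort("`chi_window` must be at least 2 frames",
                     class = "asterdrift_invalid_interval")
    dat <- tracks |>
      dplyr::group_by(.data$track_id) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        if (n < w) return(tibble::tibble(r = numeric(0), value = numeric(0)))
        purrr::map_dfr(seq_len(n - w + 1L), function(i) {
          seg <- df[i:(i + w - 1L), ]
          L <- sum(sqrt(diff(seg$x_um)^2 + diff(seg$y_um)^2))
          d_net <- sqrt((seg$x_um[w] - seg$x_um[1])^2 +
                        (seg$y_um[w] - seg$y_um[1])^2)
          tibble::tibble(r = sqrt(seg$x_um[1]^2 + seg$y_um[1]^2),
                         value = if (L > 0) d_net / L else NA_real_)
        })
      }) |>
      dplyr::ungroup() |>
      dplyr::select("r", "value")
  } else if (measure == "chi") {
    s <- track_summary(tracks)
    dat <- tibble::tibble(r = s$r_start, value = s$chi)
  } else {
    dat <- tracks |>
      dplyr::group_by(.data$track_id) |>
      dplyr::mutate(r = sqrt(.data$x_um^2 + .data$y_um^2),
                    value = c(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) /
                                diff(.data$t_s), NA_real_)) |>
      dplyr::ungroup() |>
      dplyr::select("r", "value")
  }
  dat |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(bin = cut(.data$r, breaks = breaks, right = FALSE)) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(r_lo = breaks[as.integer(.data$bin)],
                  r_hi = breaks[as.integer(.data$bin) + 1L],
                  r_mid = (.data$r_lo + .data$r_hi) / 2) |>
    dplyr::select("r_lo", "r_hi", "r_mid", "mean", "sd", "n")
}

#' Radial number density of point positions
#'
#' Counts per radial annulus, divided by annulus area, normalized so the
#' density integrates to one over the cell disk. Used to compare observed
#' MTOC position sets (e.g. from enucleated-cell controls) with uniform
#' placement.
#'
#' @param positions A data frame with columns `x_um`, `y_um`.
#' @param r_cell Cell radius (um).
#' @param bin_width Annulus width (um).
#' @return A tibble with `r_lo`, `r_hi`, `r_mid`, `count`, `density`
#'   (um^-2, integrating to 1).
#' @export
radial_density <- function(positions, r_cell = 40, bin_width = 5) {
  stopifnot(all(c("x_um", "y_um") %in% names(positions)))
  r <- sqrt(positions$x_um^2 + positions$y_um^2)
  breaks <- seq(0, r_cell + bin_width, by = bin_width)
  idx <- findInterval(r, breaks, rightmost.closed = TRUE)
  n <- length(r)
  tibble::tibble(r_lo = breaks[-length(breaks)], r_hi = breaks[-1]) |>
    dplyr::mutate(r_mid = (.data$r_lo + .data$r_hi) / 2,
                  count = vapply(seq_along(.data$r_lo),
                                 function(i) sum(idx == i), numeric(1)),
                  area = pi * (.data$r_hi^2 - .data$r_lo^2),
                  density = .data$count / (n * .data$area)) |>
    dplyr::filter(.data$r_lo < r_cell) |>
    dplyr::select("r_lo", "r_hi", "r_mid", "count", "density")
}

#' Lognormal fit to an instantaneous-speed distribution
#'
#' Maximum-likelihood lognormal fit in log space (closed form), reported as
#' the linear-scale mean and variance of the fitted distribution. Speed
#' distributions of MTOC motility are long-tailed and well described by a
#' lognormal.
#'
#' @param speeds Positive speeds (um/s); non-positive values are dropped.
#' @return A list with `mu` (linear-scale mean), `var` (linear-scale
#'   variance), `meanlog`, `sdlog`, `n`.
#' @export
fit_lognormal_velocity <- function(speeds) {
  v <- speeds[is.finite(speeds) & speeds > 0]
  if (length(v) < 10) {
    abort("need at least 10 positive speeds",
          class = "asterdrift_insufficient_data")
  }
  ml <- mean(log(v))
  sl <- sqrt(mean((log(v) - ml)^2))  # ML (n divisor)
  list(mu = exp(ml + sl^2 / 2),
       var = (exp(sl^2) - 1) * exp(2 * ml + sl^2),
       meanlog = ml, sdlog = sl, n = length(v))
}

# shared input check for trajectory tibbles
check_tracks <- function(tracks) {
  need <- c("track_id", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    abort(paste0("missing trajectory columns: ", paste(miss, collapse = ", ")),
          class = "asterdrift_parse_error")
  }
  invisible(tracks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
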