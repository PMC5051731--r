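#' Specification of a synthetic pseudo-experimental dataset
#'
#' Describes how to emulate a sparse time-lapse MTOC tracking experiment:
#' tens of tracks, frames every 3-4 minutes (jittered), total observation up
#' to ~8000 s, and isotropic Gaussian localization noise. The generator
#' drives the RWD model at fine time resolution with the reference motility
#' constants and then degrades the output to experimental sampling.
#'
#' @param n_tracks Number of tracks (the true experimental count is unknown;
#'   tens, by default 30).
#' @param frame_interval Length-2 range (s) of the jittered frame interval.
#' @param duration Total observation time (s).
#' @param noise_sd Localization noise s.d. (um).
#' @param generator `"rwd_optimal"` (reported optimal fields: attractive
#'   r_half 10, s 1; repulsive r_half 0, s 2), `"rwd_custom"` (supply
#'   `attract`/`repel`), or `"uniform_static"` (stationary uniformly placed
#'   points).
#' @param attract,repel Fields for `generator = "rwd_custom"`.
#' @param params An [rwd_params()] with the motility constants.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tracks = 30, frame_interval = c(180, 240),
                           duration = 8000, noise_sd = 0.2,
                           generator = c("rwd_optimal", "rwd_custom",
                                         "uniform_static"),
                           attract = NULL, repel = NULL,
                           params = rwd_params(), seed = 1) {
  generator <- match.arg(generator)
  stopifnot(length(frame_interval) %in% c(1L, 2L))
  if (length(frame_interval) == 1L) frame_interval <- rep(frame_interval, 2)
  if (min(frame_interval) < 60) {
    abort("`frame_interval` must be at least 60 s",
          class = "asterdrift_invalid_params")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0",
                          class = "asterdrift_invalid_params")
  if (generator == "rwd_optimal") {
    attract <- drift_field(10, 1)
    repel <- drift_field(0, 2, origin = "cell_boundary")
  }
  structure(list(n_tracks = as.integer(n_tracks),
                 frame_interval = frame_interval, duration = duration,
                 noise_sd = noise_sd, generator = generator,
                 attract = attract, repel = repel, params = params,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a pseudo-experimental MTOC tracking dataset
#'
#' Runs the RWD simulator at fine resolution, resamples each track at
#' jittered frame intervals, adds isotropic Gaussian localization noise
#' (redrawn so no sample leaves the cell and captured endpoints stay inside
#' the chromatin disk), and computes the binned reference structures -- the
#' radial directionality profile chi(r) and the capture-time distribution --
#' that [rank_scan()] consumes.
#'
#' @param spec A [synthetic_spec()].
#' @param chi_bin_width,tc_bin_width Reference bin widths (um, s).
#' @return A list with `tracks` (noisy, sparsely sampled `aster_tracks`),
#'   `reference` (list: `chi`, `t_c`, `meta`), and `spec`.
#' @export
generate_pseudo_experiment <- function(spec, chi_bin_width = 5,
                                       tc_bin_width = 600) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- spec$params
  p$n_particles <- spec$n_tracks
  p$total_time <- spec$duration
  class(p) <- "rwd_params"

  if (spec$generator == "uniform_static") {
    pts <- generate_enucleated_control(spec$n_tracks, p$r_cell)
    times <- seq(0, spec$duration, by = mean(spec$frame_interval))
    tracks <- tidyr::expand_grid(track_id = seq_len(spec$n_tracks),
                                 t_s = times) |>
      dplyr::left_join(dplyr::mutate(pts, track_id = dplyr::row_number()),
                       by = "track_id") |>
      dplyr::select("track_id", "t_s", "x_um", "y_um")
    tracks <- as_aster_tracks(tracks, p$r_cell, p$r_chr)
  } else {
    fine <- simulate_rwd(p, attract = spec$attract, repel = spec$repel,
                         record_interval = 5)
    tracks <- fine |>
      dplyr::group_by(.data$track_id) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        if (n <= 2) return(df)
        # jittered frame times, always keeping the first and final samples
        tt <- df$t_s[1]
        repeat {
          nxt <- tt[length(tt)] + runif(1, spec$frame_interval[1],
                                        spec$frame_interval[2])
          if (nxt > df$t_s[n]) break
          tt <- c(tt, nxt)
        }
        idx <- vapply(tt, function(x) which.min(abs(df$t_s - x)), integer(1))
        df[sort(unique(c(idx, 1L, n))), ]
      }) |>
      dplyr::ungroup()
    tracks <- as_aster_tracks(tracks, p$r_cell, p$r_chr)
  }

  if (spec$noise_sd > 0) {
    tracks <- add_localization_noise(tracks, spec$noise_sd,
                                     r_cell = p$r_cell, r_chr = p$r_chr)
  }

  summ <- track_summary(tracks)
  chi_ref <- radial_profile(tracks, bin_width = chi_bin_width, measure = "chi") |>
    dplyr::select("r_lo", "r_hi", "mean", "sd", "n")
  tc_breaks <- seq(0, spec$duration + tc_bin_width, by = tc_bin_width)
  n_tracks <- nrow(summ)
  tc_ref <- tibble::tibble(t_lo = tc_breaks[-length(tc_breaks)],
                           t_hi = tc_breaks[-1]) |>
    dplyr::mutate(n = vapply(seq_along(.data$t_lo), function(i) {
      sum(!is.na(summ$t_c) & summ$t_c >= .data$t_lo[i] &
            summ$t_c < .data$t_hi[i])
    }, numeric(1)),
    mean = .data$n / n_tracks,
    sd = pmax(sqrt(.data$mean * (1 - .data$mean) / n_tracks), 0.02))
  list(tracks = tracks,
       reference = list(chi = chi_ref, t_c = tc_ref,
                        meta = list(r_cell = p$r_cell, r_chr = p$r_chr,
                                    duration = spec$duration,
                                    chi_bin_width = chi_bin_width,
                                    tc_bin_width = tc_bin_width,
                                    n_tracks = n_tracks,
                                    generator = spec$generator,
                                    assumed = paste(
                                      "track count, frame jitter and noise",
                                      "floor are generator assumptions, not",
                                      "measured values"))),
       spec = spec)
}

# isotropic Gaussian noise; redrawn so samples stay in the cell and the
# capture semantics of final samples inside the chromatin disk is preserved
add_localization_noise <- function(tracks, noise_sd, r_cell, r_chr) {
  out <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      captured_end <- sqrt(df$x_um[n]^2 + df$y_um[n]^2) <= r_chr
      for (i in seq_len(n)) {
        lim <- if (i == n && captured_end) r_chr else r_cell
        repeat {
          xx <- df$x_um[i] + rnorm(1, 0, noise_sd)
          yy <- df$y_um[i] + rnorm(1, 0, noise_sd)
          if (sqrt(xx^2 + yy^2) <= lim) break
        }
        df$x_um[i] <- xx; df$y_um[i] <- yy
      }
      df
    }) |>
    dplyr::ungroup()
  as_aster_tracks(out, r_cell, r_chr)
}

#' Uniform MTOC positions emulating the enucleated-cell control
#'
#' Enucleated oocytes lose the centripetal bias and their MTOCs scatter; the
#' matching null model is uniform-by-area placement over the cell disk.
#'
#' @param n_points Number of positions (>= 1).
#' @param r_cell Cell radius (um).
#' @param seed Optional integer seed.
#' @return A tibble with `x_um`, `y_um`.
#' @export
generate_enucleated_control <- function(n_points, r_cell = 40, seed = NULL) {
  stopifnot(n_points >= 1)
  if (!is.null(seed)) set.seed(seed)
  rr <- r_cell * sqrt(runif(n_points))
  th <- runif(n_points, 0, 2 * pi)
  tibble::tibble(x_um = rr * cos(th), y_um = rr * sin(th))
}
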