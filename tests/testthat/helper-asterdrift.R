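# shared fixtures and independent oracles, built in code

# a single track from explicit coordinates
make_track <- function(t, x, y, id = 1L) {
  as_aster_tracks(tibble::tibble(track_id = id, t_s = t, x_um = x, y_um = y))
}

# straight radial track moving inward at constant speed
radial_track <- function(r0 = 30, v = 0.01, dt = 210, n = 20, id = 1L) {
  t <- seq(0, by = dt, length.out = n)
  make_track(t, r0 - v * t, rep(0, n), id = id)
}

# brute-force double-loop msd oracle (independent of track_msd)
msd_oracle <- function(t, x, y, max_lag_frac = 0.75) {
  n <- length(t)
  dt_s <- mean(diff(t))
  duration <- t[n] - t[1]
  k_max <- min(n - 1L, floor(max_lag_frac * duration / dt_s))
  out <- data.frame(lag_s = numeric(0), msd_um2 = numeric(0), n_pairs = integer(0))
  for (k in seq_len(k_max)) {
    acc <- 0
    np <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
      np <- np + 1L
    }
    out <- rbind(out, data.frame(lag_s = k * dt_s, msd_um2 = acc / np,
                                 n_pairs = np))
  }
  out
}

# noiseless drift-diffusion msd curve (Eq of the two-parameter fit model)
drift_curve <- function(d, v, lags) {
  tibble::tibble(lag_s = lags, msd_um2 = 4 * d * lags + (v * lags)^2)
}

# ring of n points at radius r0 (fixed nucleation cohort)
ring_starts <- function(n, r0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(r0 * cos(th), r0 * sin(th))
}
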