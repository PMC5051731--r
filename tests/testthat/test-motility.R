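test_that("downsampling keeps frames nearest the target grid and both ends", {
  t <- seq(0, 8000, by = 0.1)
  trk <- make_track(t, 0.001 * t, rep(20, length(t)))
  ds <- downsample_tracks(trk, 210)
  expect_lte(nrow(ds), 40)  # ~8000/210 intervals plus endpoints
  expect_equal(ds$t_s[1], 0)
  expect_equal(ds$t_s[nrow(ds)], 8000)
  expect_true(all(diff(ds$t_s) > 0))

  # identity at the native interval
  short <- make_track(seq(0, 50, 10), 1:6, rep(0, 6))
  expect_equal(as.data.frame(downsample_tracks(short, 10)),
               as.data.frame(short))
  # 2-point tracks pass through unchanged
  two <- make_track(c(0, 300), c(0, 1), c(0, 0))
  expect_equal(nrow(downsample_tracks(two, 400)), 2)
  expect_error(downsample_tracks(short, 1),
               class = "asterdrift_invalid_interval")
})

test_that("instantaneous velocity is displacement over time gap", {
  trk <- radial_track(r0 = 30, v = 0.01, dt = 210, n = 5)
  v <- instantaneous_velocities(trk)
  expect_equal(v$v_um_s, rep(0.01, 4))
  still <- make_track(c(0, 10, 20), rep(1, 3), rep(2, 3))
  expect_equal(instantaneous_velocities(still)$v_um_s, c(0, 0))
  expect_error(instantaneous_velocities(make_track(0, 1, 1)),
               class = "asterdrift_insufficient_data")
})

test_that("directionality distinguishes straight, closed and kinked paths", {
  expect_equal(track_directionality(radial_track(n = 10))$chi, 1)
  loop <- make_track(c(0, 1, 2, 3, 4), c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(track_directionality(loop)$chi, 0)
  # two equal perpendicular segments: net sqrt(2) L over path 2 L
  bent <- make_track(c(0, 1, 2), c(0, 1, 1), c(0, 0, 1))
  expect_equal(track_directionality(bent)$chi, sqrt(2) / 2)
  # zero-length path is undefined
  expect_true(is.na(track_directionality(make_track(c(0, 1), c(1, 1),
                                                    c(2, 2)))$chi))
})

test_that("msd equals the brute-force double-loop oracle exactly", {
  set.seed(42)
  for (n in c(5, 11, 20)) {
    t <- seq(0, by = 210, length.out = n)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    got <- track_msd(make_track(t, x, y))
    want <- msd_oracle(t, x, y)
    expect_equal(got$lag_s, want$lag_s)
    expect_equal(got$msd_um2, want$msd_um2)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("msd of uniform linear motion is exactly ballistic", {
  trk <- radial_track(r0 = 35, v = 0.01, dt = 210, n = 30)
  m <- track_msd(trk)
  expect_equal(m$msd_um2, (0.01 * m$lag_s)^2)
  # lag grid never exceeds 3/4 of the track duration
  expect_lte(max(m$lag_s), 0.75 * (30 - 1) * 210)
})

test_that("drift-diffusion msd fit is exact on noiseless model curves", {
  curve <- drift_curve(0.006, 0.008, seq(210, 6000, by = 210))
  fit <- fit_msd_drift(curve)
  expect_equal(fit$d_eff, 0.006, tolerance = 1e-10)
  expect_equal(fit$v_eff, 0.008, tolerance = 1e-10)

  # pure diffusion: drift term vanishes
  fit2 <- fit_msd_drift(drift_curve(0.01, 0, seq(100, 3000, by = 100)))
  expect_equal(fit2$v_eff, 0, tolerance = 1e-8)
  expect_equal(fit2$d_eff, 0.01, tolerance = 1e-10)

  # degenerate all-zero curve
  fit3 <- fit_msd_drift(tibble::tibble(lag_s = 1:5, msd_um2 = rep(0, 5)))
  expect_equal(c(fit3$d_eff, fit3$v_eff), c(0, 0))
  expect_error(fit_msd_drift(drift_curve(1, 1, c(1, 2))),
               class = "asterdrift_insufficient_data")
})

test_that("anomalous msd fit recovers exact power laws and confinement", {
  lags <- seq(210, 6000, by = 210)
  ball <- fit_msd_anomalous(tibble::tibble(lag_s = lags,
                                           msd_um2 = (0.01 * lags)^2))
  expect_equal(ball$alpha, 2, tolerance = 1e-6)
  expect_equal(ball$d_prime, 0.01^2 / 4, tolerance = 1e-6)

  diffu <- fit_msd_anomalous(tibble::tibble(lag_s = lags,
                                            msd_um2 = 4 * 0.006 * lags))
  expect_equal(diffu$alpha, 1, tolerance = 1e-6)
  expect_equal(diffu$d_prime, 0.006, tolerance = 1e-6)

  # a walk confined to a small disk saturates: alpha < 1 at long lags
  p <- rwd_params(r_cell = 5, r_chr = 0, total_time = 4000, dt = 0.1,
                  n_particles = 20, d_eff = 0.006, v_eff = 0)
  trk <- simulate_rwd(p, seed = 8, record_interval = 40)
  conf <- fit_msd_anomalous(ensemble_msd(trk))
  expect_lt(conf$alpha, 1)
})

test_that("distance-time fit recovers Hill parameters and transport mode", {
  t <- seq(0, 200, by = 5)
  for (n_true in c(0.5, 1, 2, 4)) {
    d <- 20 * t^n_true / (30^n_true + t^n_true)
    trk <- make_track(t, d, rep(0, length(t)))
    fit <- fit_distance_time(trk)
    expect_equal(fit$d_max, 20, tolerance = 1e-3)
    expect_equal(fit$t_half, 30, tolerance = 1e-3)
    expect_equal(fit$n, n_true, tolerance = 1e-3)
    expect_equal(fit$mode, if (n_true > 1) "pulling" else "pushing")
    expect_true(fit$reliable)
  }
  expect_error(fit_distance_time(make_track(0:5, rep(1, 6), rep(1, 6))),
               class = "asterdrift_fit_degenerate")
})

test_that("lognormal velocity fit matches a moment-matching oracle", {
  set.seed(9)
  v <- rlnorm(1e4, meanlog = log(8.8e-3) - 0.5 * 0.5^2, sdlog = 0.5)
  fit <- fit_lognormal_velocity(v)
  expect_equal(fit$mu, mean(v), tolerance = 0.05)
  expect_equal(fit$var, var(v), tolerance = 0.15)
  # independent ML oracle
  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    ora <- fitdistrplus::fitdist(v, "lnorm")
    expect_equal(fit$meanlog, unname(coef(ora)["meanlog"]), tolerance = 1e-3)
    expect_equal(fit$sdlog, unname(coef(ora)["sdlog"]), tolerance = 1e-2)
  }
  # near-constant speeds have near-zero variance
  cfit <- fit_lognormal_velocity(rep(0.01, 20))
  expect_lt(cfit$var, 1e-12)
  expect_error(fit_lognormal_velocity(c(0.1, 0.2)),
               class = "asterdrift_insufficient_data")
})

test_that("radial profiles bin by nucleation radius", {
  trks <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    radial_track(r0 = 5 * i + 7, v = 0.005, dt = 210, n = 6, id = i)
  }))
  trks <- as_aster_tracks(trks)
  prof <- radial_profile(trks, r_cell = 40, bin_width = 5, measure = "chi")
  expect_true(all(prof$mean == 1))  # purely radial tracks are fully directed
  expect_true(all(prof$n >= 1))
  expect_error(radial_profile(trks, bin_width = 0),
               class = "asterdrift_invalid_interval")

  # Brownian tracks: chi well below 1, roughly flat
  p <- rwd_params(n_particles = 40, total_time = 4000)
  br <- downsample_tracks(simulate_rwd(p, seed = 3, record_interval = 10), 210)
  bprof <- radial_profile(br, measure = "chi")
  expect_true(all(bprof$mean < 0.6))
})

test_that("radial density is flat for uniform points and integrates to one", {
  pts <- generate_enucleated_control(20000, r_cell = 40, seed = 2)
  dens <- radial_density(pts, r_cell = 40, bin_width = 5)
  area <- pi * (dens$r_hi^2 - dens$r_lo^2)
  expect_equal(sum(dens$density * area), 1, tolerance = 1e-12)
  expect_lt(max(dens$density) / min(dens$density), 1.25)
  # all mass at the centre
  centre <- radial_density(tibble::tibble(x_um = rep(0.5, 10),
                                          y_um = rep(0, 10)), 40, 5)
  expect_equal(centre$count[1], 10)
  expect_true(all(centre$count[-1] == 0))
})
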