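di_cyto <- list(v_g = 0.178, v_s = 0.205, f_cat = 0.075, f_res = 0.023)

test_that("bounded-regime mean MT length: closed form and simulation agree", {
  m <- mt_mean_length(di_cyto$v_g, di_cyto$v_s, di_cyto$f_cat, di_cyto$f_res)
  expect_equal(m, (0.178 * 0.205) / (0.205 * 0.075 - 0.178 * 0.023))
  expect_equal(signif(m, 2), 3.2)
  # bounded-growth condition holds for the cytoplasmic parameters
  expect_gt(di_cyto$v_s * di_cyto$f_cat, di_cyto$v_g * di_cyto$f_res)
  expect_error(mt_mean_length(0.2, 0.2, 0.01, 0.05),
               class = "asterdrift_invalid_params")

  sim <- simulate_filament_length(di_cyto$v_g, di_cyto$v_s, di_cyto$f_cat,
                                  di_cyto$f_res, total_time = 1e4, dt = 0.05,
                                  seed = 17)
  sim_mean <- mean(sim$length_um[sim$t_s > 500])
  expect_equal(sim_mean, m, tolerance = 0.1)

  # zero catastrophe: deterministic growth
  det <- simulate_filament_length(0.1, 0.2, 0, 0, total_time = 10, dt = 0.1,
                                  seed = 1)
  expect_equal(tail(det$length_um, 1), 1, tolerance = 1e-9)
})

test_that("motor force-velocity and Kramers detachment follow the model laws", {
  expect_equal(motor_load_velocity(0, 7), 2)
  expect_equal(motor_load_velocity(7, 7), 0)
  expect_equal(motor_load_velocity(10, 7), 0)        # beyond stall
  expect_equal(motor_load_velocity(3.5, 7), 1)       # linear ramp midpoint
  expect_equal(motor_load_velocity(-2, 7), 2)        # assisting load

  expect_equal(motor_detach_rate(0, 7), 1.5)
  expect_equal(motor_detach_rate(7, 7), 1.5 * exp(1))
  # detachment rate (and so mean attachment lifetime) is monotone in |f|
  f <- seq(0, 14, by = 0.5)
  expect_true(all(diff(motor_detach_rate(f, 7)) > 0))
})

test_that("motor area densities match the disk-geometry arithmetic", {
  expect_equal(motor_density(1e3, 40), 1e3 / (pi * 1600))
  expect_equal(motor_density(1e3, 40), 0.199, tolerance = 0.002)
  expect_equal(motor_density(1e4, 40), 1.989, tolerance = 0.002)
})

test_that("gradient mapping concentrates motors and stabilizes MTs near chromatin", {
  f <- drift_field(10, 1)
  anchors <- sample_motor_gradient(10000, f, seed = 23)
  r <- sqrt(anchors$x_um^2 + anchors$y_um^2)
  expect_true(all(r <= 40))
  # empirical radial histogram vs the area-weighted field, integrated over
  # each bin (the sigmoid varies too sharply for a midpoint rule)
  br <- seq(0, 40, by = 4)
  counts <- as.numeric(table(cut(r, br)))
  bin_mass <- vapply(seq_len(length(br) - 1), function(i) {
    rr <- seq(br[i], br[i + 1], length.out = 200)
    phi <- field_weight(f, pmax(0, rr - 10))
    sum(phi * 2 * pi * rr) * diff(rr[1:2])
  }, numeric(1))
  expected <- bin_mass / sum(bin_mass) * length(r)
  keep <- expected >= 5
  x2 <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  expect_lt(x2, qchisq(0.999, sum(keep) - 1))

  # dynamic-instability interpolation hits the stabilized values at chromatin
  di <- map_di_gradient(c(0, 40), f)
  expect_equal(di$f_cat[1], 0.0397, tolerance = 1e-3)
  expect_equal(di$f_res[1], 0.0122, tolerance = 1e-3)
  expect_equal(di$f_cat[2], 0.075, tolerance = 1e-6)
  expect_equal(di$f_res[2], 0.023, tolerance = 1e-6)
})

test_that("bending, confinement and cross-linking forces behave mechanically", {
  # straight (collinear) filament: zero bending force
  vx <- seq(0, 3, by = 0.5); vy <- rep(0, length(vx))
  expect_true(all(bending_forces(vx, vy) == 0))
  # bent filament: forces appear and sum to zero (no net self-force)
  vy2 <- c(0, 0, 0.2, 0, 0, 0, 0)
  fb <- bending_forces(vx, vy2)
  expect_gt(max(abs(fb)), 0)
  expect_equal(colSums(fb), c(0, 0), tolerance = 1e-12)

  # interior filament feels no confinement
  expect_true(all(cortical_forces(vx + 10, vy, r_cell = 40) == 0))
  # protruding filament: net inward force, capped at the Euler load
  fc <- cortical_forces(seq(38, 41, by = 0.5), rep(0, 7), r_cell = 40,
                        len = 3)
  expect_lt(sum(fc[, 1]), 0)
  expect_lte(sqrt(sum(colSums(fc)^2)), pi^2 * 20 / (4 * 9) + 1e-9)

  # cross-linker: Hookean, equal and opposite; 10 nm at 0.1 pN/nm -> 1 pN
  cf <- clustering_force(c(0, 0), c(0.01, 0), k_mot = 0.1)
  expect_equal(cf$f1, c(1, 0))
  expect_equal(cf$f1 + cf$f2, c(0, 0))
  expect_equal(clustering_force(c(1, 1), c(1, 1))$f1, c(0, 0))
})

test_that("zero-temperature, zero-motor interior asters are exactly static", {
  cfg <- aster_config("no_gradient", preset = "smoke", n_mtoc = 3, n_mi = 0,
                      total_time = 30, k_B_T = 0)
  # interior ring: far enough from the cortex that no filament can touch it
  run <- run_scenario(cfg, seed = 2, start = ring_starts(3, 20))
  spread <- run$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(d = max(abs(x_um - x_um[1]) + abs(y_um - y_um[1])))
  expect_true(all(spread$d == 0))
  expect_equal(run$diagnostics$max_pair_imbalance, 0)
})

test_that("thermal MTOC diffusion satisfies the Einstein relation", {
  # bare MTOCs (no filaments): D = kBT / (6 pi eta a)
  cfg <- aster_config("no_gradient", preset = "smoke", n_mtoc = 25, n_mt = 0,
                      n_mi = 0, total_time = 60, record_interval = 1)
  run <- run_scenario(cfg, seed = 6)
  fit <- fit_msd_drift(ensemble_msd(run$tracks))
  d_theory <- (4.1e-21 * 1e18) / (6 * pi * 0.05 * 0.2)
  expect_equal(fit$d_eff, d_theory, tolerance = 0.3)
})

test_that("filament lengths in the engine hold the dynamic-instability mean", {
  cfg <- aster_config("no_gradient", preset = "smoke", n_mtoc = 4, n_mi = 0,
                      total_time = 120)
  run <- run_scenario(cfg, seed = 12)
  expect_equal(mean(run$mean_filament_length$length_um), 3.23, tolerance = 0.2)
  expect_true(all(run$mean_filament_length$length_um > 0))
})

test_that("a single anchored motor drags the aster to its anchor", {
  set.seed(3)
  x <- asterdrift:::motor_pull_debug_cpp(2, 0.01, 30, 0.01, 0, 7)
  # approach toward the anchor, settling at anchor minus rim radius; once
  # pinned, any residual wobble stays within the stability step cap
  expect_equal(mean(tail(x, 200)), 1.8, tolerance = 0.1)
  reach <- which(x > 1.5)[1]
  expect_true(all(diff(x[1:reach]) >= -1e-9))  # monotone while walking
})

test_that("aster speed during motor transport is bounded by the motor speed", {
  set.seed(3)
  x <- asterdrift:::motor_pull_debug_cpp(2, 0.01, 5, 0.01, 0, 7)
  # sustained transport window, after the initial spring transient has
  # relaxed and before the rim pins at the anchor
  win <- which(x > 0.3 & x < 1.5)
  expect_gt(length(win), 20)
  expect_lte(max(diff(x[win])) / 0.01, 2 + 1e-6)
})

test_that("cross-linking complexes pull neighbouring asters together", {
  cfg <- aster_config("clustering", preset = "smoke", n_mtoc = 2, n_mt = 20,
                      n_mc = 2000, total_time = 60)
  run <- run_scenario(cfg, seed = 9, start = cbind(c(18, 22), c(0, 0)))
  d <- run$tracks |>
    tidyr::pivot_wider(names_from = track_id, values_from = c(x_um, y_um)) |>
    dplyr::mutate(d = sqrt((x_um_1 - x_um_2)^2 + (y_um_1 - y_um_2)^2))
  expect_true(run$diagnostics$any_crosslink)
  expect_lt(tail(d$d, 1), d$d[1])
})

test_that("mean MTOC speed is insensitive to MTs per aster", {
  # transport speed at 2-min framing (fine framing is dominated by thermal
  # jitter, which scales with aster drag rather than motor activity)
  v_for <- function(n_mt, seed) {
    cfg <- aster_config("motor_gradient", preset = "smoke", n_mtoc = 8,
                        n_mt = n_mt, n_mi = 1000, total_time = 240)
    run <- run_scenario(cfg, seed = seed, start = ring_starts(8, 25))
    mean(instantaneous_velocities(downsample_tracks(run$tracks, 120))$v_um_s)
  }
  v20 <- v_for(20, 14)
  v120 <- v_for(120, 14)
  expect_lt(abs(v120 - v20) / max(v20, v120), 0.5)
})
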