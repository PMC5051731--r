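test_that("Brownian step speed matches 2D diffusion statistics", {
  expect_equal(brownian_speed(0.006, 0.1), sqrt(0.24))
  expect_equal(brownian_speed(0, 0.1), 0)
  # square-root scaling: quadrupling D doubles the speed
  expect_equal(brownian_speed(4 * 0.006, 0.1), 2 * brownian_speed(0.006, 0.1))
  expect_error(brownian_speed(0.006, 0), class = "asterdrift_invalid_timestep")
})

test_that("step-state weight limits reduce to pure drift or pure diffusion", {
  p <- rwd_params()
  all_drift <- drift_field(Inf, 1)

  set.seed(1)
  s1 <- step_state(c(25, 0), p, attract = all_drift)
  expect_equal(s1$w_a, 1)
  expect_equal(s1$speed, p$v_eff)
  expect_equal(s1$theta_net, s1$theta_dr)  # toward the centre, exactly

  set.seed(2)
  s2 <- step_state(c(25, 0), p,
                   repel = drift_field(Inf, 1, origin = "cell_boundary"))
  expect_equal(s2$w_r, 1)
  expect_equal(s2$speed, p$v_eff)
  expect_equal(s2$theta_net, s2$theta_dr)

  # no fields: Brownian speed and uniform angles
  set.seed(3)
  draws <- purrr::map_dfr(1:400, ~ step_state(c(25, 0), p))
  expect_true(all(draws$speed == brownian_speed(p$d_eff, p$dt)))
  circ_diff <- (draws$theta_net - draws$theta_df + pi) %% (2 * pi) - pi
  expect_lt(max(abs(circ_diff)), 1e-9)
  resultant <- sqrt(mean(cos(draws$theta_net))^2 + mean(sin(draws$theta_net))^2)
  expect_lt(resultant, 0.12)  # ~2/sqrt(n) for uniform angles

  expect_error(step_state(c(50, 0), p), class = "asterdrift_domain_error")
})

test_that("pure-drift capture time equals distance over speed for any start", {
  for (r0 in c(12, 25, 38)) {
    p <- rwd_params(n_particles = 1, d_eff = 0)
    trk <- simulate_rwd(p, attract = drift_field(Inf, 1), seed = 7,
                        start = matrix(c(r0, 0), 1))
    expect_equal(track_summary(trk)$t_c, (r0 - p$r_chr) / p$v_eff,
                 tolerance = p$dt / 100)
  }
})

test_that("particles stay in the cell and capture terminates tracks", {
  p <- rwd_params(n_particles = 30, total_time = 2000)
  trk <- simulate_rwd(p, attract = drift_field(10, 1),
                      repel = drift_field(0, 2, origin = "cell_boundary"),
                      seed = 4, record_interval = 5)
  r <- sqrt(trk$x_um^2 + trk$y_um^2)
  expect_true(all(r <= p$r_cell + 1e-9))
  # absorbing chromatin: at most the final sample lies inside r_chr
  inside <- trk |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(n_in = sum(sqrt(x_um^2 + y_um^2) <= 10),
                     last_in = sqrt(dplyr::last(x_um)^2 +
                                    dplyr::last(y_um)^2) <= 10)
  expect_true(all(inside$n_in <= 1))
  expect_true(all(inside$n_in == 0 | inside$last_in))
})

test_that("simulations are bit-reproducible under a fixed seed", {
  p <- rwd_params(n_particles = 5, total_time = 500)
  a <- simulate_rwd(p, attract = drift_field(10, 1), seed = 99)
  b <- simulate_rwd(p, attract = drift_field(10, 1), seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("stationary parameters give stationary particles", {
  p <- rwd_params(n_particles = 5, total_time = 200, d_eff = 0, v_eff = 0)
  trk <- simulate_rwd(p, seed = 5, record_interval = 10)
  s <- track_summary(trk)
  expect_true(all(is.na(s$t_c)))
  spread <- trk |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(d = max(abs(x_um - x_um[1]) + abs(y_um - y_um[1])))
  expect_true(all(spread$d == 0))
})

test_that("timestep validation recovers the input diffusion coefficient", {
  err <- validate_timestep(dt = 0.1, d = 0.006, n_particles = 100,
                           total_time = 8000, seed = 21)
  expect_lt(err, 0.1)
  expect_equal(validate_timestep(dt = 0.1, d = 0, n_particles = 10,
                                 total_time = 100, seed = 1), 0)
  expect_error(validate_timestep(0.1, 0.006, n_particles = 1),
               class = "asterdrift_insufficient_sample")
})
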