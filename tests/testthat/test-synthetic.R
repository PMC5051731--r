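test_that("pseudo-experiment generation is seed-deterministic", {
  spec <- synthetic_spec(n_tracks = 8, seed = 4)
  a <- generate_pseudo_experiment(spec)
  b <- generate_pseudo_experiment(spec)
  expect_identical(as.data.frame(a$tracks), as.data.frame(b$tracks))
  expect_identical(a$reference$chi, b$reference$chi)
})

test_that("sparse sampling and noise respect the cell geometry", {
  pe <- generate_pseudo_experiment(synthetic_spec(n_tracks = 15, seed = 6,
                                                  noise_sd = 1))
  r <- sqrt(pe$tracks$x_um^2 + pe$tracks$y_um^2)
  expect_true(all(r <= 40 + 1e-9))
  # captured tracks still end inside the chromatin disk after noise
  s <- track_summary(pe$tracks)
  cap <- dplyr::filter(s, !is.na(t_c))
  expect_gt(nrow(cap), 0)
  ends <- pe$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(r_end = sqrt(dplyr::last(x_um)^2 + dplyr::last(y_um)^2))
  expect_true(all(ends$r_end[ends$track_id %in% cap$track_id] <= 10 + 1e-9))
  # frame intervals lie in the jitter window (the final gap of each track is
  # set by the preserved endpoint, not the frame clock)
  gaps <- pe$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(gap = diff(t_s), pos = seq_along(gap), n = dplyr::n())
  interior <- gaps$gap[gaps$pos < gaps$n - 1]
  expect_true(all(interior >= 170 & interior <= 250))
})

test_that("without jitter the frame grid is regular", {
  pe <- generate_pseudo_experiment(synthetic_spec(n_tracks = 5, seed = 2,
                                                  frame_interval = 210,
                                                  noise_sd = 0))
  gaps <- pe$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(gap = diff(t_s), pos = seq_along(gap), n = dplyr::n())
  interior <- gaps$gap[gaps$pos < gaps$n - 1]
  expect_true(all(abs(interior - 210) <= 5 + 1e-9))  # snapped to the 5 s grid
})

test_that("the generated chi profile is U-shaped across the cell", {
  prof <- purrr::map_dfr(1:5, function(s) {
    pe <- generate_pseudo_experiment(synthetic_spec(n_tracks = 30, seed = s))
    radial_profile(pe$tracks, bin_width = 5, measure = "chi", chi_window = 4)
  })
  agg <- prof |>
    dplyr::group_by(r_lo) |>
    dplyr::summarise(mean = sum(mean * n) / sum(n))
  lo <- min(agg$mean)
  expect_gte(agg$mean[1] - lo, 0.1)
  expect_gte(agg$mean[nrow(agg)] - lo, 0.1)
})

test_that("generator calibration: speeds near the experimental scale", {
  pe <- generate_pseudo_experiment(synthetic_spec(n_tracks = 30, seed = 11))
  v <- mean(instantaneous_velocities(pe$tracks)$v_um_s)
  expect_gt(v, 8.7e-3 / 2)
  expect_lt(v, 8.7e-3 * 2)
})

test_that("enucleated control is uniform by area over the disk", {
  pts <- generate_enucleated_control(4000, r_cell = 40, seed = 5)
  r <- sqrt(pts$x_um^2 + pts$y_um^2)
  expect_true(all(r <= 40))
  expect_equal(mean(r), 2 / 3 * 40, tolerance = 0.01)
  one <- generate_enucleated_control(1, r_cell = 40, seed = 1)
  expect_equal(nrow(one), 1)
  expect_lte(sqrt(one$x_um^2 + one$y_um^2), 40)
})
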