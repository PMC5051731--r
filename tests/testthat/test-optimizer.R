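test_that("weighted rmse error matches hand-computed cases", {
  # perfect agreement
  expect_equal(weighted_error(1:3, 1:3, rep(1, 3), rep(5, 3))$epsilon, 0)

  # single point outside the one-sigma band: w = w_m = 2
  out <- weighted_error(0, 1, 0.1, 10)
  expect_equal(out$epsilon, sqrt(2), tolerance = 1e-12)
  expect_equal(out$weights, 2)

  # single point inside the band with n_i = n_max: w = 1, eps = |e - s|
  ins <- weighted_error(0.95, 1, 0.1, 10)
  expect_equal(ins$epsilon, 0.05, tolerance = 1e-12)
  expect_equal(ins$weights, 1)

  # in-band weights scale as n_i / n_max
  two <- weighted_error(c(1, 2), c(1.05, 2.05), c(0.1, 0.1), c(5, 10))
  expect_equal(two$weights, c(0.5, 1))

  expect_error(weighted_error(1:2, 1:3, rep(1, 3), rep(1, 3)),
               class = "asterdrift_invalid_params")
})

test_that("the default grid has 600 parameter sets", {
  expect_equal(nrow(param_grid()), 600)
})

test_that("rank tables are valid rankings and a single set is trivially best", {
  pe <- generate_pseudo_experiment(synthetic_spec(n_tracks = 15, seed = 3))
  g1 <- param_grid(a_rhalf = 10, a_s = 1, r_rhalf = 0, r_s = 2)
  rs <- rank_scan(g1, pe$reference,
                  params = rwd_params(n_particles = 10, total_time = 2000),
                  replicates = 1, seed = 5)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$sum_rank, 2)

  g <- param_grid(a_rhalf = c(5, 10), a_s = 1, r_rhalf = c(0, 4), r_s = 2)
  rs2 <- rank_scan(g, pe$reference,
                   params = rwd_params(n_particles = 10, total_time = 2000),
                   replicates = 1, seed = 6)
  k <- nrow(g)
  expect_equal(sum(rs2$rank_chi), k * (k + 1) / 2)
  expect_equal(sum(rs2$rank_tc), k * (k + 1) / 2)
  expect_equal(rs2$sum_rank, rs2$rank_chi + rs2$rank_tc)
  expect_equal(rs2$sum_rank[1], min(rs2$sum_rank))
})

test_that("the scan recovers the generating attractive field", {
  pe <- generate_pseudo_experiment(synthetic_spec(n_tracks = 30, seed = 13))
  grid <- param_grid(a_rhalf = c(0, 5, 10, 20), a_s = 1, r_rhalf = c(0, 4),
                     r_s = 2)
  rs <- rank_scan(grid, pe$reference,
                  params = rwd_params(n_particles = 40),
                  replicates = 2, seed = 31, record_interval = 30)
  best <- attr(rs, "best")
  expect_equal(best$a_rhalf, 10)
})
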