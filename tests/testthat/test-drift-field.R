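test_that("sigmoid field takes its defining values", {
  f <- drift_field(r_half = 10, s = 1)
  expect_equal(field_weight(f, 10), 0.5)
  expect_equal(field_weight(f, 0), 1 / (1 + exp(-10)))
  expect_lt(field_weight(f, 1e3), 1e-12)

  # monotone non-increasing in r, values in (0, 1)
  r <- seq(0, 60, by = 0.5)
  w <- field_weight(f, r)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w > 0 & w < 1))

  # degenerate all-drift field
  expect_equal(field_weight(drift_field(Inf, 1), c(0, 100)), c(1, 1))
})

test_that("invalid fields and domains are rejected", {
  expect_error(drift_field(10, 0), class = "asterdrift_invalid_field")
  expect_error(drift_field(10, -1), class = "asterdrift_invalid_field")
  expect_error(drift_field(-5, 1), class = "asterdrift_invalid_field")
  expect_error(field_weight(drift_field(10, 1), -1),
               class = "asterdrift_domain_error")
})
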