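# Growth-curve families and the constraint-based exclusion argument.

test_that("growth curves evaluate to their closed forms", {
  lg <- growth_curve_spec("logistic", r = 2, V0 = 2, V_max = 4, t0 = 13.5)
  far <- growth_curve(lg, c(13.5, 40))
  expect_equal(far$volume[1], 2)             # midpoint start
  expect_equal(far$volume[2], 4, tolerance = 1e-10)   # asymptote
  # midpoint slope r * V_max / 4
  eps <- 1e-6
  num_slope <- diff(growth_curve(lg, c(13.5 - eps, 13.5 + eps))$volume) / (2 * eps)
  expect_equal(num_slope, 2 * 4 / 4, tolerance = 1e-5)

  flat <- growth_curve(growth_curve_spec("linear", c = 0, V0 = 1), 13:17)
  expect_true(all(flat$volume == 1))

  # zero delay reduces the delayed model exactly to the control curve
  d0 <- growth_curve_spec("delayed_logistic", r = 2, V0 = 0.25, t_delay = 0)
  c0 <- growth_curve_spec("logistic", r = 2, V0 = 0.25)
  tt <- seq(13.5, 17.5, by = 0.25)
  expect_equal(growth_curve(d0, tt)$volume, growth_curve(c0, tt)$volume)

  # lag freezes growth until the lag elapses
  lag <- growth_curve_spec("lag_logistic", r = 2, V0 = 0.25, t_lag = 1)
  expect_equal(growth_curve(lag, c(13.5, 14.0, 14.5))$volume[1:2],
               c(0.25, 0.25))
  expect_error(growth_curve_spec("sigmoid"), class = "nichegrowth_usage_error")
  expect_error(growth_curve_spec("logistic", V0 = 5, V_max = 4),
               class = "nichegrowth_validation_error")
})

test_that("default constraints leave exactly the delayed-development model standing", {
  v <- evaluate_hypotheses()
  expect_equal(sum(v$consistent), 1L)
  expect_equal(v$family[v$consistent], "delayed_logistic")
  # every rejected family names at least one violated constraint
  rejected <- v[!v$consistent, ]
  expect_true(all(lengths(rejected$violated_constraints) >= 1L))
  expect_true(all(lengths(v$violated_constraints[v$consistent]) == 0L))
})

test_that("relaxing individual constraints re-admits the corresponding families", {
  # no E14.5 deficit: the rapid-cycle rejection ground disappears
  v1 <- evaluate_hypotheses(constraint_set(ratio_at_E14_5 = 1))
  row1 <- v1[v1$family == "rapid_cycle", ]
  expect_false(any(grepl("E14.5", unlist(row1$violated_constraints))))
  # significant apoptosis: the lag model is no longer rejected on that ground
  v2 <- evaluate_hypotheses(constraint_set(apoptosis_insignificant = FALSE))
  expect_true(v2$consistent[v2$family == "lag_logistic"])
})

test_that("hypothesis curves plot as a family portrait", {
  expect_s3_class(plot_hypotheses(), "ggplot")
})
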