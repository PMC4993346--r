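# Integration, calibration, plateau detection, neuron output, and the
# apoptosis sensitivity sweep.

test_that("the degenerate one-stage cycle grows exactly exponentially", {
  cfg <- one_phase_config(9.2, t_end = 14.5)
  traj <- simulate_niche(cfg)
  ratio <- stats::approx(traj$times, traj$observables$V_VZ, 14.5)$y /
    traj$observables$V_VZ[1]
  expect_equal(ratio, exp(24 / 9.2), tolerance = 1e-3)
})

test_that("the unconstrained growth rate matches the Euler-Lotka root", {
  cfg <- pure_proliferation_config(t_end = 16.5)
  traj <- simulate_niche(cfg)
  lam <- euler_lotka_rate(c(3.1, 4.0, 1.6, 0.5))       # per hour
  idx <- traj$times >= 15.5
  slope <- stats::coef(stats::lm(log(traj$observables$V_VZ[idx]) ~ traj$times[idx]))[[2]]
  expect_equal(slope, 24 * lam, tolerance = 1e-3)
  # single-stage sanity: the root is the inverse stage time
  expect_equal(euler_lotka_rate(9.2), 1 / 9.2, tolerance = 1e-10)
})

test_that("Erlang sub-staging slows unconstrained growth toward the fixed-duration limit", {
  # exponential stages overshoot the deterministic doubling rate; Erlang
  # sub-stages pull the realized rate back toward log(2)/transit
  slope_of <- function(m) {
    cfg <- model_config(fate = fate_rule(4, 20L), p_override = 1,
                        t_start = 13.5, t_end = 15.5, erlang_m = m)
    tr <- simulate_niche(cfg, dt = 0.05)
    idx <- tr$times >= 15.0
    stats::coef(stats::lm(log(tr$observables$V_VZ[idx]) ~ tr$times[idx]))[[2]]
  }
  s1 <- slope_of(1L); s3 <- slope_of(3L)
  expect_equal(s1, 24 * euler_lotka_rate(c(3.1, 4.0, 1.6, 0.5), m = 1),
               tolerance = 1e-2)
  expect_equal(s3, 24 * euler_lotka_rate(c(3.1, 4.0, 1.6, 0.5), m = 3),
               tolerance = 1e-2)
  expect_lt(s3, s1)
  expect_gt(s3, 24 * log(2) / 9.2)
})

test_that("simulation is deterministic and converged in the integrator grid", {
  cfg <- default_config()
  t1 <- simulate_niche(cfg)
  t2 <- simulate_niche(cfg)
  expect_identical(t1$states, t2$states)
  tight <- simulate_niche(cfg, rtol = 5e-9, atol = 5e-11)
  rel <- abs(utils::tail(tight$observables$V_combined, 1) -
               utils::tail(t1$observables$V_combined, 1)) /
    utils::tail(t1$observables$V_combined, 1)
  expect_lt(rel, 1e-6)
})

test_that("calibration is a fixed point at its own output and near-linear far from capacity", {
  cfg <- default_config()
  cal <- calibrate_initial_volume(cfg, 4.0, 14.5)
  expect_true(cal$converged)
  expect_equal(cal$achieved_target, 4.0, tolerance = 1e-6)
  # fixed point: the simulated volume of the calibrated run calibrates to itself
  again <- calibrate_initial_volume(cal$config, 4.0, 14.5)
  expect_equal(again$initial_volume, cal$initial_volume, tolerance = 1e-4)
  # far below capacity the map is near-linear in the initial volume
  lo1 <- calibrate_initial_volume(cfg, 0.02, 14.5)
  lo2 <- calibrate_initial_volume(cfg, 0.04, 14.5)
  expect_equal(lo2$initial_volume / lo1$initial_volume, 2, tolerance = 0.05)
  expect_error(calibrate_initial_volume(cfg, 1e6, 14.5),
               class = "nichegrowth_calibration_error")
  expect_error(calibrate_initial_volume(cfg, 4, 13.0),
               class = "nichegrowth_usage_error")
})

test_that("plateau detection finds constructed peaks and flags monotone series", {
  base <- simulate_niche(default_config(), dt = 0.05)
  peaked <- base
  peaked$observables$V_VZ <- exp(-(peaked$observables$time - 15.0)^2)
  pk <- plateau_time(peaked, "VZ")
  expect_equal(pk$t_peak, 15.0)
  expect_false(pk$still_growing)

  rising <- base
  rising$observables$V_VZ <- plogis(rising$observables$time - 15)
  pk2 <- plateau_time(rising, "VZ")
  expect_true(pk2$still_growing)
  expect_equal(pk2$t_peak, 17.5)
})

test_that("cumulative neuron output is a window integral of production", {
  traj <- calibrated_trajectory("control")
  expect_equal(cumulative_neuron_output(traj, c(15, 15)), 0)
  a <- cumulative_neuron_output(traj, c(14.5, 16))
  b <- cumulative_neuron_output(traj, c(16, 17.5))
  expect_equal(a + b, cumulative_neuron_output(traj, c(14.5, 17.5)))
  expect_gt(a, 0)
  expect_error(cumulative_neuron_output(traj, c(16, 15)),
               class = "nichegrowth_usage_error")

  # pure self-renewal: over one mean cycle each radial glia yields ~one neuron
  cfg <- model_config(fate = fate_rule(V_max = 4, K = 40L), p_override = 0,
                      t_start = 13.5, t_end = 15.5)
  tr <- simulate_niche(cfg)
  cyc_days <- transit_time(cfg, "II") / 24
  out <- cumulative_neuron_output(tr, c(13.5 + 2 * cyc_days, 13.5 + 3 * cyc_days))
  expect_equal(out, cfg$initial_volume, tolerance = 0.1)
})

test_that("apoptosis drag is zero at fold 0, monotone, and small at the measured scale", {
  cfg <- default_config(apoptosis = apoptosis_measured(1))
  tab <- apoptosis_sensitivity(cfg, c(0, 1, 2.5, 5))
  expect_equal(tab$deficit[tab$fold == 0], 0)
  expect_true(all(diff(tab$deficit) >= 0))
  # the measured 5-fold elevation shaves a sliver of growth - nowhere near
  # the ~75% deficit a lag-phase explanation of the 4-fold gap would need
  expect_lt(tab$deficit[tab$fold == 5], 0.3)
  ins <- apoptosis_insignificance(cfg, fold = 5)
  expect_lt(ins$rate_ratio, 0.1)
  expect_true(ins$insignificant)
})

test_that("genotype comparison: the mutant niche trails, then closes the gap", {
  ctrl <- calibrated_trajectory("control")
  mut <- calibrated_trajectory("mutant")
  oc <- ctrl$observables; om <- mut$observables
  mid <- oc$time > 13.5 & oc$time < 15.5
  expect_true(all(om$V_combined[mid] < oc$V_combined[mid]))
  gap <- oc$V_combined - om$V_combined
  expect_lt(gap[oc$time == 17.5], gap[oc$time == 14.5])  # compensatory growth
  # control radial glia progress monotonically toward their division cap
  mrd <- oc$mean_remaining_divisions
  expect_true(all(diff(mrd[!is.na(mrd)]) <= 1e-9))
})

test_that("trajectory tidiers and plots expose the observables", {
  traj <- calibrated_trajectory("control")
  td <- tidy(traj)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("time", "V_VZ", "V_SVZ", "cum_neuron_production") %in% names(td)))
  gl <- glance(traj)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$K, 5L)
  expect_s3_class(autoplot(traj), "ggplot")
  cal <- calibrate_initial_volume(default_config(), 4, 14.5)
  expect_true(tidy(cal)$converged)
})
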