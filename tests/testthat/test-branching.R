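# Mean-field validity: the exact stochastic branching simulation of the same
# rates reproduces the ODE trajectory.

test_that("Gillespie branching means match the ODE within Monte-Carlo error", {
  cfg <- default_config()
  cfg$t_end <- 14.0
  ode <- simulate_niche(cfg)
  o_end <- ode$observables[nrow(ode$observables), ]

  reps <- lapply(1:5, function(s)
    simulate_branching(cfg, n0 = 10000L, record_times = 14.0, seed = s))
  vz <- vapply(reps, function(b) b$V_VZ, numeric(1))
  vc <- vapply(reps, function(b) b$V_combined, numeric(1))
  nn <- vapply(reps, function(b) b$cum_neuron_production, numeric(1))

  expect_lt(abs(mean(vz) - o_end$V_VZ), 3 * stats::sd(vz))
  expect_lt(abs(mean(vc) - o_end$V_combined), 3 * stats::sd(vc))
  expect_lt(abs(mean(nn) - o_end$cum_neuron_production), 3 * stats::sd(nn))
  # and in relative terms the mean-field approximation is tight at 1e4 cells
  expect_lt(abs(mean(vc) / o_end$V_combined - 1), 0.02)
})

test_that("the stochastic simulator hits the exact law in the single-stage limit", {
  cfg <- one_phase_config(9.2, t_end = 14.0)
  reps <- vapply(1:4, function(s)
    simulate_branching(cfg, n0 = 5000L, record_times = 14.0, seed = s)$V_VZ,
    numeric(1))
  expect_lt(abs(mean(reps) - exp(12 / 9.2)), 3 * stats::sd(reps))
})

test_that("branching output is reproducible under a fixed seed", {
  cfg <- default_config()
  cfg$t_end <- 13.7
  a <- simulate_branching(cfg, n0 = 2000L, record_times = 13.7, seed = 11)
  b <- simulate_branching(cfg, n0 = 2000L, record_times = 13.7, seed = 11)
  expect_identical(a, b)
})
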