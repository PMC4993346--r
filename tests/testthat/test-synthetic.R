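# Synthetic specimens, marker forward models, and end-to-end fold-change
# recovery through the stereology pipeline.

make_group <- function(genotype, n, true_volume, apoptotic_fraction, seed0) {
  lapply(seq_len(n), function(i) {
    generate_specimen(specimen_spec(genotype, true_volume = true_volume,
                                    apoptotic_fraction = apoptotic_fraction,
                                    seed = seed0 + i))
  })
}

test_that("specimen generation is deterministic in the seed and degenerates gracefully", {
  sp <- specimen_spec("control", true_volume = 1e8, seed = 42)
  a <- generate_specimen(sp)
  b <- generate_specimen(sp)
  expect_identical(a$cavalieri, b$cavalieri)
  expect_identical(a$fractionator, b$fractionator)

  dead <- generate_specimen(specimen_spec("control", true_volume = 0, seed = 1))
  expect_true(dead$degenerate)
  expect_equal(nrow(dead$cavalieri), 0)

  empty <- generate_specimen(specimen_spec("control", true_volume = 1e8,
                                           true_cell_density = 0, seed = 3))
  expect_true(all(empty$fractionator$count == 0))
})

test_that("specimens tied to a trajectory inherit its truths", {
  traj <- calibrated_trajectory("control")
  sp <- specimen_spec("control", age = 14.5, trajectory = traj, seed = 5)
  expect_equal(sp$true_volume, 4 * 8e7, tolerance = 1e-4)
  expect_named(sp$markers, c("BrdU", "Ki67", "pH3"))
  expect_equal(sp$inm_true, 0.375)
  m <- generate_specimen(sp)
  est <- cavalieri_volume(m$cavalieri$count)
  expect_equal(est / sp$true_volume, 1, tolerance = 0.25)  # one noisy specimen
})

test_that("marker fractions follow the phase-occupancy forward model", {
  cfg <- default_config()
  all_s <- marker_fractions(cfg, c(G1 = 0, S = 1, G2 = 0, M = 0), pulse = 0)
  expect_equal(all_s$BrdU, 1)
  expect_equal(all_s$Ki67, 1)
  expect_equal(all_s$pH3, 0)
  mixed <- marker_fractions(cfg, c(G1 = 0.3, S = 0.2, G2 = 0.05, M = 0.05),
                            pulse = 0.5)
  expect_equal(mixed$Ki67, 0.6)
  expect_equal(mixed$pH3, 0.05)
  expect_equal(mixed$BrdU, 0.2 + 0.5 / 9.2 * 0.3)
  expect_error(marker_fractions(cfg, c(G1 = 0.8, S = 0.5, G2 = 0, M = 0)),
               class = "nichegrowth_domain_error")
})

test_that("the pH3/BrdU ratio matches the stable stage distribution oracle", {
  # independent oracle: stable-stage occupancies of a 4-stage exponential
  # cycle growing at the Euler-Lotka rate
  d <- c(G1 = 3.1, S = 4.0, G2 = 1.6, M = 0.5)
  lam <- euler_lotka_rate(d)
  r <- 1 / d
  n <- numeric(4)
  n[1] <- 1
  for (i in 2:4) n[i] <- n[i - 1] * r[i - 1] / (lam + r[i])
  n[1] <- n[1] / (lam + r[1]) * (lam + r[1])  # n1 set by normalisation only
  occ <- n / sum(n)

  cfg <- pure_proliferation_config(t_end = 16.5)
  traj <- simulate_niche(cfg)
  ob <- traj$observables[nrow(traj$observables), ]
  expect_equal(ob$frac_M / ob$frac_S, occ[4] / occ[2], tolerance = 1e-2)

  mk <- marker_fractions(cfg, c(G1 = ob$frac_G1, S = ob$frac_S,
                                G2 = ob$frac_G2, M = ob$frac_M), pulse = 0)
  expect_equal(mk$pH3 / mk$BrdU, occ[4] / occ[2], tolerance = 1e-2)
  # and the duration-ratio approximation is in the right ballpark
  expect_equal(mk$pH3 / mk$BrdU, d[["M"]] / d[["S"]], tolerance = 0.35)
})

test_that("S-phase elongation lowers the CldU-at-ventricle fraction", {
  expect_equal(inm_ventricle_fraction(4, 2.5, 1), 0.375)
  expect_equal(inm_ventricle_fraction(5, 2.5, 1), 0.30)
  expect_equal(inm_ventricle_fraction(4, 0.5, 1), 0)   # chase shorter than delay
  expect_error(inm_ventricle_fraction(4, -1, 1), class = "nichegrowth_domain_error")
  ctrl <- default_config(); mut <- default_config("mutant")
  expect_lt(inm_ventricle_fraction(mut$phases$t_S, 2.5, 1),
            inm_ventricle_fraction(ctrl$phases$t_S, 2.5, 1))
})

test_that("mutant marker fractions exceed control at matched relative niche fullness", {
  # at P0-like epochs the mutant niche sits earlier on its growth curve, so a
  # larger share of its volume is cycling; compare at matched fullness
  ctrl <- calibrated_trajectory("control")$observables
  mut <- calibrated_trajectory("mutant")$observables
  at_fullness <- function(obs, frac) obs[which.min(abs(obs$V_VZ / max(obs$V_VZ) - frac)), ]
  oc <- at_fullness(ctrl, 0.9); om <- at_fullness(mut, 0.9)
  mk <- function(cfg, ob) {
    share <- (ob$V_VZ + ob$V_IP) / ob$V_combined
    marker_fractions(cfg, c(G1 = ob$frac_G1, S = ob$frac_S, G2 = ob$frac_G2,
                            M = ob$frac_M) * share, pulse = 0.5)
  }
  expect_gt(mk(default_config("mutant"), om)$BrdU,
            mk(default_config("control"), oc)$BrdU)
})

test_that("identical groups give unit folds; injected folds are recovered", {
  g <- make_group("control", 3, 2e8, 0.005, 100)
  same <- fold_change_summary(g, g, n_boot = 200, seed = 1)
  expect_true(all(abs(same$fold - 1) < 1e-12))

  ctrl <- make_group("control", 10, 3.2e8, 0.002, 1000)
  mut <- make_group("mutant", 10, 0.8e8, 0.010, 2000)
  folds <- fold_change_summary(ctrl, mut, n_boot = 1000, seed = 7)
  vol <- folds[folds$readout == "volume", ]
  apo <- folds[folds$readout == "apoptosis_density", ]
  expect_true(vol$lo <= 4 && 4 <= vol$hi)
  expect_true(apo$lo <= 5 && 5 <= apo$hi)
  expect_equal(vol$fold, 4, tolerance = 0.15)
  expect_equal(apo$fold, 5, tolerance = 0.3)

  # single-specimen groups: fold reported, interval flagged unavailable
  one <- fold_change_summary(g[1], g[1], n_boot = 50)
  expect_false(any(one$interval_available))
  expect_true(all(is.na(one$lo)))
})
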