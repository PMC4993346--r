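# Cavalieri and optical-fractionator estimators: exact arithmetic,
# linearity, and design-based unbiasedness on known synthetic solids.

test_that("Cavalieri arithmetic matches the sampling design exactly", {
  des <- cavalieri_design()   # 30 um grid, 50 um sections, 1-in-5
  expect_equal(cavalieri_volume(c(60, 40), des), 2.25e7)  # 100 * 900 * 50 * 5
  expect_equal(cavalieri_volume(c(0, 0, 0), des), 0)
  counts <- c(13, 27, 8)
  expect_equal(cavalieri_volume(2 * counts, des), 2 * cavalieri_volume(counts, des))
  expect_error(cavalieri_volume(integer(0), des), class = "nichegrowth_usage_error")
  expect_error(cavalieri_volume(c(1, -2), des), class = "nichegrowth_validation_error")
})

test_that("fractionator arithmetic inverts the three sampling fractions", {
  des <- stereology_preset("fractionator_caspase3")
  expect_equal(fractionator_count(c(25, 15), des), 5001.75)  # 40 * 125.04375
  expect_equal(fractionator_count(0, des), 0)
  half_frame <- fractionator_design(frame = c(50, 25))
  expect_equal(fractionator_count(40, half_frame), 2 * fractionator_count(40, des))
  expect_error(fractionator_design(frame = c(500, 500)),
               class = "nichegrowth_validation_error")
  expect_error(fractionator_design(dissector_height = 60),
               class = "nichegrowth_validation_error")
})

test_that("Cavalieri point counting is unbiased over random grid placements", {
  set.seed(101)
  V <- 2.25e7
  semi <- ellipsoid_semiaxes(V)
  des <- cavalieri_design()
  est <- replicate(10000, cavalieri_volume(sample_cavalieri_counts(semi), des))
  expect_lt(abs(mean(est) / V - 1), 0.01)
  expect_equal(4 / 3 * pi * prod(semi), V)
})

test_that("fractionator counting is unbiased for a known-intensity cell population", {
  truth <- 3.2e8 * 1e-3 * 0.01   # volume x density x apoptotic fraction
  des <- stereology_preset("fractionator_caspase3")
  est <- vapply(1:4000, function(s) {
    sp <- specimen_spec("control", true_volume = 3.2e8,
                        apoptotic_fraction = 0.01, seed = s)
    fractionator_count(generate_specimen(sp)$fractionator$caspase_count, des)
  }, numeric(1))
  expect_lt(abs(mean(est) / truth - 1), 0.01)
})

test_that("denser section sampling reduces estimator variance", {
  set.seed(202)
  semi <- ellipsoid_semiaxes(2.25e7)
  d5 <- cavalieri_design(section_interval = 5)
  d10 <- cavalieri_design(section_interval = 10)
  e5 <- replicate(3000, cavalieri_volume(sample_cavalieri_counts(semi, d5), d5))
  e10 <- replicate(3000, cavalieri_volume(sample_cavalieri_counts(semi, d10), d10))
  expect_lt(stats::var(e5), stats::var(e10))
})

test_that("the Gundersen CE is small for dense systematic counts", {
  p <- round(150 * sqrt(pmax(1 - ((1:9 - 5) / 5)^2, 0)))
  ce <- gundersen_ce(p, shape_factor = 4)
  expect_gt(ce, 0)
  expect_lt(ce, 0.1)
  expect_error(gundersen_ce(c(3, 4)), class = "nichegrowth_usage_error")
})
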