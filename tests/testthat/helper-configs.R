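# Shared fixture builders for the suite (all constructed in code).

# unconstrained proliferation: p forced to 1, cap far out of reach
pure_proliferation_config <- function(t_end = 14.5, K = 20L, ...) {
  model_config(fate = fate_rule(V_max = 4, K = K), p_override = 1,
               t_start = 13.5, t_end = t_end, ...)
}

# degenerate single-stage cycle: the whole cycle is one exponential stage
one_phase_config <- function(mean_hours = 9.2, t_end = 14.5, K = 30L) {
  model_config(phases = phase_durations(mean_hours, mean_hours, mean_hours,
                                        0, 0, 0),
               fate = fate_rule(V_max = 4, K = K), p_override = 1,
               t_start = 13.5, t_end = t_end)
}

# calibrated genotype trajectories, computed once per test run
calibrated_trajectory <- local({
  cache <- list()
  function(genotype = "control") {
    if (is.null(cache[[genotype]])) {
      target <- if (genotype == "control") 4 else 1
      cal <- calibrate_initial_volume(default_config(genotype), target, 14.5)
      cache[[genotype]] <<- simulate_niche(cal$config)
    }
    cache[[genotype]]
  }
})
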