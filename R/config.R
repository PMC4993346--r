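# Model parameterisation: phase durations, fate rule, apoptosis, auxiliary
# timings, genotype modifiers, and the assembled model configuration.

PHASES <- c("G1", "S", "G2", "M")

#' Cell-cycle phase durations
#'
#' Mean durations (hours) of the radial-glia cell-cycle phases. G1 carries
#' three values, one per prospective division type: `t_G1P` for symmetric
#' proliferative (Type I) divisions, `t_G1R` for asymmetric self-renewing
#' (Type II) divisions, and `t_G1D` for terminal differentiating (Type III)
#' divisions. G1 lengthens toward differentiation, so `t_G1P <= t_G1R <=
#' t_G1D` is enforced. The defaults reproduce a 9.2 h Type I transit time
#' with an S+G2 block of 5.6 h.
#'
#' @param t_G1P,t_G1R,t_G1D G1 duration (hours) for Type I/II/III divisions.
#' @param t_S,t_G2,t_M S, G2 and M durations (hours).
#' @return A `niche_phases` object (named list of durations).
#' @export
#' @examples
#' phase_durations()
phase_durations <- function(t_G1P = 3.1, t_G1R = 9.3, t_G1D = 13.0,
                            t_S = 4.0, t_G2 = 1.6, t_M = 0.5) {
  x <- list(t_G1P = t_G1P, t_G1R = t_G1R, t_G1D = t_G1D,
            t_S = t_S, t_G2 = t_G2, t_M = t_M)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort_validation(sprintf("phase duration '%s' must be a single finite number", nm))
    }
    # G1 pools must be strictly positive; S/G2/M may be exactly zero, which
    # collapses the phase (used for degenerate single-stage analytic limits)
    min_ok <- if (grepl("^t_G1", nm)) v > 0 else v >= 0
    if (!min_ok) {
      abort_validation(sprintf("phase duration '%s' must be %s", nm,
                               if (grepl("^t_G1", nm)) "> 0" else ">= 0"))
    }
  }
  if (!(t_G1P <= t_G1R && t_G1R <= t_G1D)) {
    abort_validation("G1 ordering violated: need t_G1P <= t_G1R <= t_G1D")
  }
  structure(x, class = "niche_phases")
}

#' Fate rule: carrying capacity and division cap
#'
#' @param V_max Carrying capacity of the VZ in model volume units; the
#'   proliferative fraction is `p = 1 - V_VZ / V_max` (clamped to `[0, 1]`).
#' @param K Number of divisions available before terminal differentiation
#'   (control default 5; the mutant transformation adds one).
#' @return A `niche_fate` object.
#' @export
fate_rule <- function(V_max = 4.0, K = 5L) {
  if (!is.numeric(V_max) || length(V_max) != 1L || !is.finite(V_max) || V_max <= 0) {
    abort_validation("V_max must be a single positive number")
  }
  if (length(K) != 1L || !is.finite(K) || K < 0 || K != round(K)) {
    abort_validation("K must be a non-negative integer")
  }
  structure(list(V_max = V_max, K = as.integer(K)), class = "niche_fate")
}

#' Apoptosis specification
#'
#' Per-phase entry rates into the apoptotic state and the mean residence time
#' of apoptotic cells before clearance. Rates are per hour, one per phase for
#' each cycling compartment (radial glia, intermediate progenitors).
#'
#' @param delta_RG,delta_IP Named numeric vectors over `G1, S, G2, M` (per
#'   hour). A single scalar is recycled to all four phases.
#' @param t_clear Mean residence (hours) in the apoptotic compartment before
#'   clearance.
#' @return A `niche_apoptosis` object.
#' @export
apoptosis_spec <- function(delta_RG = 0, delta_IP = 0, t_clear = 2.0) {
  expand <- function(v, who) {
    if (length(v) == 1L) v <- stats::setNames(rep(as.numeric(v), 4L), PHASES)
    if (is.null(names(v))) names(v) <- PHASES
    if (!all(PHASES %in% names(v))) {
      abort_validation(sprintf("%s apoptosis rates must name phases G1, S, G2, M", who))
    }
    v <- v[PHASES]
    if (any(!is.finite(v)) || any(v < 0)) {
      abort_validation(sprintf("%s apoptosis rates must be finite and >= 0", who))
    }
    v
  }
  if (!is.numeric(t_clear) || length(t_clear) != 1L || !is.finite(t_clear) || t_clear <= 0) {
    abort_validation("t_clear must be a single positive number")
  }
  structure(list(delta_RG = expand(delta_RG, "RG"),
                 delta_IP = expand(delta_IP, "IP"),
                 t_clear = t_clear),
            class = "niche_apoptosis")
}

#' Measured-scale apoptosis preset
#'
#' Baseline per-phase apoptosis rate chosen so the apoptotic compartment
#' occupies roughly 0.1% of the cycling niche under rapid (2 h) clearance,
#' matching the rarity of cleaved-caspase-3-positive cells in the embryonic
#' VZ/SVZ. `fold` scales all rates, e.g. `fold = 5` for the mutant's
#' elevated apoptosis.
#'
#' @param fold Multiplier on the baseline rates.
#' @param baseline Baseline per-phase rate (per hour).
#' @inheritParams apoptosis_spec
#' @return A `niche_apoptosis` object.
#' @export
apoptosis_measured <- function(fold = 1, baseline = 5e-4, t_clear = 2.0) {
  if (fold < 0) abort_validation("fold must be >= 0")
  apoptosis_spec(delta_RG = baseline * fold, delta_IP = baseline * fold,
                 t_clear = t_clear)
}

#' Auxiliary timings and unit conversion
#'
#' @param t_IP_cycle Total intermediate-progenitor cycle time (hours) for its
#'   single G1->S->G2->M pass before dividing into two migratory neurons.
#' @param t_migrate Mean residence (hours) of a newborn neuron in the VZ/SVZ
#'   before migrating out (the migration flow).
#' @param unit_cell_volume Cell volume (um^3) used to convert between model
#'   volume units and cell counts at the reporting layer.
#' @return A `niche_aux` object.
#' @export
auxiliary_spec <- function(t_IP_cycle = 14.0, t_migrate = 24.0,
                           unit_cell_volume = 1000) {
  x <- list(t_IP_cycle = t_IP_cycle, t_migrate = t_migrate,
            unit_cell_volume = unit_cell_volume)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort_validation(sprintf("auxiliary parameter '%s' must be a single positive number", nm))
    }
  }
  structure(x, class = "niche_aux")
}

#' Genotype modifier
#'
#' A perturbation applied to a control configuration to produce a mutant one:
#' S and G2 are multiplied by `sg2_elongation`, the division cap K is shifted
#' by `K_delta`, and all apoptosis entry rates are scaled by
#' `apoptosis_scale`. The default is the cyclin-A2-null transformation: 25%
#' S/G2 elongation with one extra available division.
#'
#' @param sg2_elongation Factor (>= 1) applied to `t_S` and `t_G2`.
#' @param K_delta Integer added to the division cap K.
#' @param apoptosis_scale Factor applied to every apoptosis entry rate.
#' @return A `niche_modifier` object.
#' @export
#' @examples
#' genotype_modifier()            # the mutant transformation
#' genotype_modifier(1, 0, 1)     # identity
genotype_modifier <- function(sg2_elongation = 1.25, K_delta = 1L,
                              apoptosis_scale = 1.0) {
  # > 0 (not >= 1) so that the inverse of a modifier is itself a modifier;
  # biological loss-of-function perturbations use factors >= 1
  if (!is.numeric(sg2_elongation) || sg2_elongation <= 0) {
    abort_validation("sg2_elongation must be > 0")
  }
  if (K_delta != round(K_delta)) abort_validation("K_delta must be an integer")
  if (apoptosis_scale < 0) abort_validation("apoptosis_scale must be >= 0")
  structure(list(sg2_elongation = sg2_elongation,
                 K_delta = as.integer(K_delta),
                 apoptosis_scale = apoptosis_scale),
            class = "niche_modifier")
}

#' Assemble a full model configuration
#'
#' @param phases A [phase_durations()] object.
#' @param fate A [fate_rule()] object.
#' @param apoptosis An [apoptosis_spec()] object.
#' @param aux An [auxiliary_spec()] object.
#' @param t_start,t_end Simulation window in embryonic days (E13.5 -> 13.5).
#' @param initial_volume Total radial-glia volume at `t_start` (model units).
#' @param initial_age Mitotic age (divisions already undergone) of all radial
#'   glia at `t_start`; must not exceed K.
#' @param p_override Optional fixed proliferative fraction in `[0, 1]`,
#'   replacing the logistic rule (used for analytic limit checks).
#' @param erlang_m Number of Erlang sub-stages per cell-cycle phase
#'   (1 = exponential stage times, the default; larger values approximate
#'   fixed durations).
#' @param division_yield Daughter volume produced per unit of mother volume
#'   at mitosis (2 = volume doubling, the biological default; 1 makes
#'   division volume-conserving, useful for bookkeeping checks).
#' @return A validated `niche_config` object.
#' @export
model_config <- function(phases = phase_durations(), fate = fate_rule(),
                         apoptosis = apoptosis_spec(), aux = auxiliary_spec(),
                         t_start = 13.5, t_end = 17.5,
                         initial_volume = 1.0, initial_age = 0L,
                         p_override = NULL, erlang_m = 1L,
                         division_yield = 2.0) {
  cfg <- structure(list(phases = phases, fate = fate, apoptosis = apoptosis,
                        aux = aux, t_start = t_start, t_end = t_end,
                        initial_volume = initial_volume,
                        initial_age = as.integer(initial_age),
                        p_override = p_override,
                        erlang_m = as.integer(erlang_m),
                        division_yield = division_yield),
                   class = "niche_config")
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every structural invariant and returns the configuration
#' invisibly-unchanged, or signals a validation error naming the violated
#' invariant.
#'
#' @param config A `niche_config` object.
#' @return The validated configuration.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "niche_config")) abort_usage("not a niche_config object")
  if (!inherits(config$phases, "niche_phases")) abort_validation("phases block invalid")
  if (!inherits(config$fate, "niche_fate")) abort_validation("fate block invalid")
  if (!inherits(config$apoptosis, "niche_apoptosis")) abort_validation("apoptosis block invalid")
  if (!inherits(config$aux, "niche_aux")) abort_validation("aux block invalid")
  if (!(config$t_start < config$t_end)) abort_validation("t_start must be < t_end")
  if (config$initial_volume <= 0) abort_validation("initial_volume must be > 0")
  if (config$initial_age < 0 || config$initial_age > config$fate$K) {
    abort_validation("initial_age must lie in 0..K")
  }
  if (!is.null(config$p_override)) {
    p <- config$p_override
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      abort_validation("p_override must be a single value in [0, 1]")
    }
  }
  if (config$erlang_m < 1L) abort_validation("erlang_m must be >= 1")
  if (config$division_yield <= 0) abort_validation("division_yield must be > 0")
  invisible(config)
}

#' Default configurations for the two genotypes
#'
#' The control configuration carries the default phase durations (Type I
#' transit 9.2 h), division cap K = 5 and carrying capacity 4 volume units;
#' `genotype = "mutant"` applies the default genotype modifier (25% S/G2
#' elongation, K = 6).
#'
#' @param genotype `"control"` or `"mutant"`.
#' @param apoptosis Optional [apoptosis_spec()]; defaults to the all-zero
#'   "clean" model.
#' @param ... Passed on to [model_config()].
#' @return A `niche_config`.
#' @export
#' @examples
#' transit_time(default_config(), "I")            # 9.2
#' transit_time(default_config("mutant"), "I")    # 10.6
default_config <- function(genotype = c("control", "mutant"),
                           apoptosis = apoptosis_spec(), ...) {
  genotype <- match.arg(genotype)
  cfg <- model_config(apoptosis = apoptosis, ...)
  if (genotype == "mutant") cfg <- apply_genotype(cfg, genotype_modifier())
  cfg
}

#' Apply a genotype modifier to a configuration
#'
#' Returns a new configuration with S and G2 durations multiplied by the
#' modifier's elongation factor, K shifted, and apoptosis rates scaled; the
#' input is not modified.
#'
#' @param config A `niche_config`.
#' @param modifier A [genotype_modifier()].
#' @return A new validated `niche_config`.
#' @export
apply_genotype <- function(config, modifier) {
  validate_config(config)
  if (!inherits(modifier, "niche_modifier")) abort_usage("not a niche_modifier object")
  ph <- config$phases
  phases <- phase_durations(t_G1P = ph$t_G1P, t_G1R = ph$t_G1R, t_G1D = ph$t_G1D,
                            t_S = ph$t_S * modifier$sg2_elongation,
                            t_G2 = ph$t_G2 * modifier$sg2_elongation,
                            t_M = ph$t_M)
  fate <- fate_rule(V_max = config$fate$V_max, K = config$fate$K + modifier$K_delta)
  ap <- config$apoptosis
  apoptosis <- apoptosis_spec(delta_RG = ap$delta_RG * modifier$apoptosis_scale,
                              delta_IP = ap$delta_IP * modifier$apoptosis_scale,
                              t_clear = ap$t_clear)
  out <- config
  out$phases <- phases
  out$fate <- fate
  out$apoptosis <- apoptosis
  validate_config(out)
  out
}

#' Mean transit time of one division type
#'
#' Total cycle time `t_G1(type) + t_S + t_G2 + t_M`, where the G1 duration is
#' selected by the division type (I proliferative, II self-renewing,
#' III terminal).
#'
#' @param config A `niche_config`.
#' @param division_type `"I"`, `"II"` or `"III"`.
#' @return Transit time in hours.
#' @export
transit_time <- function(config, division_type = c("I", "II", "III")) {
  validate_config(config)
  division_type <- tryCatch(match.arg(division_type),
                            error = function(e) abort_usage("unknown division type"))
  ph <- config$phases
  g1 <- switch(division_type, I = ph$t_G1P, II = ph$t_G1R, III = ph$t_G1D)
  g1 + ph$t_S + ph$t_G2 + ph$t_M
}

#' Effective population-average G1 duration
#'
#' The convex mixture `p * t_G1P + (1 - p - q) * t_G1R + q * t_G1D`, where
#' `p` is the share of proliferative (Type I) mitoses and `q` the share of
#' terminal (Type III) mitoses.
#'
#' @param p,q Mixture weights, non-negative with `p + q <= 1`.
#' @param phases A [phase_durations()] object.
#' @return Effective G1 duration in hours.
#' @export
effective_g1_time <- function(p, q, phases = phase_durations()) {
  if (!inherits(phases, "niche_phases")) abort_usage("phases must be a niche_phases object")
  if (any(p < 0) || any(q < 0) || any(p + q > 1 + 1e-12)) {
    abort_domain("weights must satisfy p >= 0, q >= 0, p + q <= 1")
  }
  p * phases$t_G1P + (1 - p - q) * phases$t_G1R + q * phases$t_G1D
}

#' Division-budget difference between two cycle lengths
#'
#' Number of divisions elapsed over a time window at one mean cycle time
#' minus the number elapsed at another — the arithmetic behind "one extra
#' available division" for a lineage whose cycle lengthened from
#' cre onset onward.
#'
#' @param window_hours Length of the window (hours), e.g. 72 for E10.5->E13.5.
#' @param t_fast,t_slow Mean cycle times (hours).
#' @return Difference in elapsed divisions (fast minus slow).
#' @export
#' @examples
#' division_budget_difference(72, 9.2, 10.6)  # ~1 extra division available
division_budget_difference <- function(window_hours, t_fast, t_slow) {
  if (window_hours < 0 || t_fast <= 0 || t_slow <= 0) {
    abort_domain("window must be >= 0 and cycle times > 0")
  }
  window_hours / t_fast - window_hours / t_slow
}

# error helpers ---------------------------------------------------------------

abort_validation <- function(msg) rlang::abort(msg, class = "nichegrowth_validation_error")
abort_config <- function(msg) rlang::abort(msg, class = "nichegrowth_config_error")
abort_usage <- function(msg) rlang::abort(msg, class = "nichegrowth_usage_error")
abort_domain <- function(msg) rlang::abort(msg, class = "nichegrowth_domain_error")
abort_numerical <- function(msg) rlang::abort(msg, class = "nichegrowth_numerical_error")

#' @export
print.niche_config <- function(x, ...) {
  ph <- x$phases
  cat("<niche_config>\n")
  cat(sprintf("  phases (h): G1P=%.2f G1R=%.2f G1D=%.2f S=%.2f G2=%.2f M=%.2f\n",
              ph$t_G1P, ph$t_G1R, ph$t_G1D, ph$t_S, ph$t_G2, ph$t_M))
  cat(sprintf("  fate: V_max=%.3g, K=%d; window E%.1f-E%.1f; V0=%.4g at age %d\n",
              x$fate$V_max, x$fate$K, x$t_start, x$t_end,
              x$initial_volume, x$initial_age))
  cat(sprintf("  Type I transit: %.3g h; apoptosis t_clear=%.2g h\n",
              transit_time(x, "I"), x$apoptosis$t_clear))
  invisible(x)
}
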