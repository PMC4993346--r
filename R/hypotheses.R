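# Candidate growth explanations for the mutant forebrain and the
# constraint-based exclusion argument that leaves only developmental delay.

HYPOTHESIS_FAMILIES <- c("logistic", "rapid_cycle", "lag_logistic",
                         "linear", "delayed_logistic")

#' Growth-curve specification
#'
#' Closed-form growth families used to compare hypotheses for the mutant's
#' volume trajectory: plain logistic growth, logistic with a faster
#' intrinsic rate (`rapid_cycle`), logistic preceded by a lag phase
#' (`lag_logistic`), linear growth of a fixed-size proliferative pool
#' (`linear`), and logistic shifted later in time (`delayed_logistic`, the
#' developmental-delay model).
#'
#' @param family One of `"logistic"`, `"rapid_cycle"`, `"lag_logistic"`,
#'   `"linear"`, `"delayed_logistic"`.
#' @param r Intrinsic growth rate (per day).
#' @param V0 Volume at `t0`.
#' @param V_max Carrying capacity (logistic families; requires `V0 < V_max`).
#' @param t0 Reference day at which `V = V0`.
#' @param t_lag Lag duration (days; `lag_logistic`).
#' @param t_delay Onset shift (days; `delayed_logistic`).
#' @param c Slope (volume/day; `linear`).
#' @param rate_scale Multiplier on `r` for `rapid_cycle` (> 1).
#' @return A `niche_growth_spec`.
#' @export
growth_curve_spec <- function(family, r = 2.0, V0 = 0.25, V_max = 4.0,
                              t0 = 13.5, t_lag = 0, t_delay = 0, c = 0.5,
                              rate_scale = 1.5) {
  if (!family %in% HYPOTHESIS_FAMILIES) abort_usage("unknown growth-curve family")
  if (r <= 0 || V0 <= 0) abort_validation("r and V0 must be > 0")
  if (family != "linear" && V0 >= V_max) {
    abort_validation("logistic families require V0 < V_max")
  }
  if (t_lag < 0 || t_delay < 0) abort_validation("lags/delays must be >= 0")
  if (family == "rapid_cycle" && rate_scale <= 1) {
    abort_validation("rapid_cycle requires rate_scale > 1")
  }
  structure(list(family = family, r = r, V0 = V0, V_max = V_max, t0 = t0,
                 t_lag = t_lag, t_delay = t_delay, c = c,
                 rate_scale = rate_scale),
            class = "niche_growth_spec")
}

#' Evaluate a growth curve
#'
#' Closed-form evaluation of a [growth_curve_spec()]:
#' `V(t) = V_max / (1 + ((V_max - V0)/V0) exp(-r (t - t0)))` for the
#' logistic families, with the growth time replaced by
#' `max(t - t0 - t_lag, 0)` (lag), shifted onset (delay), or `r` scaled
#' (rapid cycle); `V(t) = V0 + c (t - t0)` for the linear family.
#'
#' @param spec A `niche_growth_spec`.
#' @param times Increasing vector of days.
#' @return Tibble with `time`, `volume`, `family`.
#' @export
growth_curve <- function(spec, times) {
  if (!inherits(spec, "niche_growth_spec")) abort_usage("not a niche_growth_spec")
  if (is.unsorted(times)) abort_usage("times must be increasing")
  logi <- function(tau, r) spec$V_max /
    (1 + (spec$V_max - spec$V0) / spec$V0 * exp(-r * tau))
  v <- switch(spec$family,
    logistic = logi(times - spec$t0, spec$r),
    rapid_cycle = logi(times - spec$t0, spec$r * spec$rate_scale),
    lag_logistic = logi(pmax(times - spec$t0 - spec$t_lag, 0), spec$r),
    delayed_logistic = logi(times - spec$t0 - spec$t_delay, spec$r),
    linear = spec$V0 + spec$c * (times - spec$t0)
  )
  tibble::tibble(time = times, volume = v, family = spec$family)
}

#' Constraint set for hypothesis exclusion
#'
#' The measured facts every candidate growth explanation must satisfy: the
#' mutant niche is about 4-fold smaller at E14.5, not significantly
#' different by E17.5 (within `parity_band`), apoptosis is elevated about
#' 5-fold yet dynamically insignificant.
#'
#' @param ratio_at_E14_5 Control/mutant combined-volume fold at E14.5.
#' @param ratio_at_E17_5 Control/mutant fold at E17.5 (parity = 1).
#' @param parity_band Relative half-width of the "not significant" band at
#'   E17.5 (default 0.25).
#' @param apoptosis_fold Observed mutant/control apoptosis fold.
#' @param apoptosis_insignificant Whether simulated growth is insensitive to
#'   that apoptosis elevation (see [apoptosis_sensitivity()]).
#' @return A `niche_constraints` object.
#' @export
constraint_set <- function(ratio_at_E14_5 = 4, ratio_at_E17_5 = 1,
                           parity_band = 0.25, apoptosis_fold = 5,
                           apoptosis_insignificant = TRUE) {
  if (ratio_at_E14_5 <= 0 || ratio_at_E17_5 <= 0 || apoptosis_fold <= 0) {
    abort_validation("folds must be > 0")
  }
  structure(list(ratio_at_E14_5 = ratio_at_E14_5,
                 ratio_at_E17_5 = ratio_at_E17_5,
                 parity_band = parity_band,
                 apoptosis_fold = apoptosis_fold,
                 apoptosis_insignificant = apoptosis_insignificant),
            class = "niche_constraints")
}

#' Constraint-based exclusion of growth hypotheses
#'
#' Encodes the argument that eliminates each alternative explanation of the
#' mutant's growth, as executable checks: a more rapid cycle would require
#' the mutant niche to be *larger* at E14.5 (it is 4-fold smaller, and the
#' missing S-phase cyclin makes faster transit implausible); a prolonged lag
#' phase would require apoptosis far above what is measured (the simulated
#' dynamics are insensitive to the observed elevation); linear fixed-pool
#' growth reaching parity at E17.5 from a 4-fold deficit would require
#' apoptosis comparable to proliferation or a single-cell-type niche; the
#' delayed-development model is consistent if it meets both volume-ratio
#' constraints. With the default constraints exactly one family survives.
#'
#' @param constraints A [constraint_set()].
#' @param shared Named list of shared control-reference curve parameters
#'   (`r`, `V0`, `V_max`), used to check the delayed model's ratios. The
#'   default `r = log(5)` per day makes a one-day shift of the control curve
#'   reproduce the 4-fold E14.5 deficit exactly from `V0 = V_max / 16`.
#' @param t_delay Delay (days) of the candidate delayed-development curve
#'   (default one day, the approximate lag of the mutant niche).
#' @return Tibble with one row per family: `family`, `consistent`,
#'   `violated_constraints` (list-column of reason strings, empty when
#'   consistent).
#' @export
evaluate_hypotheses <- function(constraints = constraint_set(),
                                shared = list(r = log(5), V0 = 0.25, V_max = 4.0),
                                t_delay = 1.0) {
  if (!inherits(constraints, "niche_constraints")) abort_usage("not a niche_constraints")
  verdicts <- list(
    logistic = character(0),
    rapid_cycle = character(0),
    lag_logistic = character(0),
    linear = character(0),
    delayed_logistic = character(0)
  )

  # the plain control logistic is the reference for the *control*; as an
  # explanation of the mutant it fails the E14.5 deficit
  if (constraints$ratio_at_E14_5 > 1 + constraints$parity_band) {
    verdicts$logistic <- c(verdicts$logistic,
      "same-curve growth cannot produce the E14.5 volume deficit")
    verdicts$rapid_cycle <- c(verdicts$rapid_cycle,
      "a faster cycle implies mutant volume >= control at E14.5, contradicting the measured deficit")
  }
  if (constraints$apoptosis_insignificant) {
    verdicts$lag_logistic <- c(verdicts$lag_logistic,
      "measured apoptosis elevation is dynamically insignificant, too small to produce a lag phase")
  }
  if (constraints$ratio_at_E14_5 > 1 + constraints$parity_band &&
      abs(constraints$ratio_at_E17_5 - 1) <= constraints$parity_band) {
    verdicts$linear <- c(verdicts$linear,
      "fixed-pool growth reaching E17.5 parity from the E14.5 deficit requires apoptosis ~ proliferation or a single-cell-type niche")
  }

  # the delayed model must reproduce both measured ratios with shared
  # logistic parameters and a time shift
  ctrl <- growth_curve_spec("logistic", r = shared$r, V0 = shared$V0,
                            V_max = shared$V_max)
  delayed <- growth_curve_spec("delayed_logistic", r = shared$r, V0 = shared$V0,
                               V_max = shared$V_max, t_delay = t_delay)
  at <- function(spec, t) growth_curve(spec, t)$volume
  r145 <- at(ctrl, 14.5) / at(delayed, 14.5)
  r175 <- at(ctrl, 17.5) / at(delayed, 17.5)
  if (abs(r145 / constraints$ratio_at_E14_5 - 1) > constraints$parity_band) {
    verdicts$delayed_logistic <- c(verdicts$delayed_logistic,
      sprintf("delayed curve gives E14.5 fold %.2f, outside the measured %.2f band",
              r145, constraints$ratio_at_E14_5))
  }
  if (abs(r175 / constraints$ratio_at_E17_5 - 1) > constraints$parity_band) {
    verdicts$delayed_logistic <- c(verdicts$delayed_logistic,
      sprintf("delayed curve gives E17.5 fold %.2f, outside the parity band", r175))
  }

  tibble::tibble(
    family = names(verdicts),
    consistent = vapply(verdicts, length, integer(1L)) == 0L,
    violated_constraints = unname(verdicts)
  )
}
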