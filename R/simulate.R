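# Trajectory integration, initial-volume calibration, and the headline
# simulation readouts: plateau timing, cumulative neuron output, and the
# apoptosis sensitivity sweep.

#' Simulate the niche model over embryonic time
#'
#' Integrates the model from `t_start` to `t_end` with an adaptive-step
#' solver (lsoda; relative tolerance 1e-8, absolute 1e-10 by default) and
#' dense output on a regular grid. The initial state places all radial-glia
#' volume at `initial_age`, with phase occupancy weighted by the time spent
#' in each phase.
#'
#' @param config A `niche_config`.
#' @param dt Output grid spacing in days.
#' @param rtol,atol Integrator tolerances.
#' @return A `niche_trajectory`: list with `times` (days), `states` (matrix,
#'   one row per time), `observables` (tibble, one row per time, including a
#'   `time` column), `config`, and `config_fingerprint`. Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @export
#' @examples
#' traj <- simulate_niche(default_config(), dt = 0.05)
#' dplyr::slice_tail(tidy(traj), n = 1)
simulate_niche <- function(config, dt = 0.01, rtol = 1e-8, atol = 1e-10) {
  validate_config(config)
  P <- build_model(config)
  y0 <- initial_state(config, P$layout)
  times <- seq(config$t_start, config$t_end, by = dt)
  if (utils::tail(times, 1L) < config$t_end) times <- c(times, config$t_end)

  sol <- tryCatch(
    deSolve::ode(y = y0, times = times, func = rhs_core, parms = P,
                 method = "lsoda", rtol = rtol, atol = atol),
    error = function(e) abort_numerical(sprintf("integrator failure: %s",
                                                conditionMessage(e)))
  )
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    abort_numerical("integrator returned an incomplete or non-finite trajectory")
  }
  states <- unname(sol[, -1L, drop = FALSE])
  colnames(states) <- P$layout$names
  if (max(states) > 1e6 * max(config$initial_volume, config$fate$V_max)) {
    rlang::abort("trajectory diverged beyond the volume cap",
                 class = "nichegrowth_divergence_error")
  }
  # tiny integrator-tolerance negatives are clamped for reporting
  states[states < 0 & states > -1e-8] <- 0
  obs <- observables(states, config)
  obs <- tibble::add_column(obs, time = times, .before = 1L)

  structure(list(times = times, states = states, observables = obs,
                 config = config,
                 config_fingerprint = config_fingerprint(config)),
            class = "niche_trajectory")
}

#' @export
print.niche_trajectory <- function(x, ...) {
  cat(sprintf("<niche_trajectory> E%.2f-E%.2f, %d time points, K=%d (fingerprint %s)\n",
              min(x$times), max(x$times), length(x$times), x$config$fate$K,
              x$config_fingerprint))
  last <- x$observables[nrow(x$observables), ]
  cat(sprintf("  final: V_VZ=%.4g V_SVZ=%.4g cumulative neurons=%.4g\n",
              last$V_VZ, last$V_SVZ, last$cum_neuron_production))
  invisible(x)
}

#' Calibrate the initial radial-glia volume to a measured target
#'
#' Root-finds the `t_start` initial volume so the simulated combined VZ/SVZ
#' volume at `target_time` equals `target_volume`. The volume-at-target map
#' is monotone in the initial volume, so a bracketed search over
#' `[1e-6, 10 * V_max]` converges reliably.
#'
#' @param config A `niche_config`.
#' @param target_volume Measured combined VZ/SVZ volume (model units), > 0.
#' @param target_time Embryonic day in `(t_start, t_end]`.
#' @param tol Relative convergence tolerance on the achieved volume.
#' @return A `niche_calibration`: list with `initial_volume`,
#'   `achieved_target`, `target_volume`, `iterations`, `converged`, and the
#'   calibrated `config` (its `initial_volume` replaced).
#' @export
calibrate_initial_volume <- function(config, target_volume, target_time,
                                     tol = 1e-6) {
  validate_config(config)
  if (target_volume <= 0) abort_usage("target_volume must be > 0")
  if (target_time <= config$t_start || target_time > config$t_end) {
    abort_usage("target_time must lie in (t_start, t_end]")
  }
  short <- config
  short$t_end <- target_time
  iters <- 0L
  vol_at_target <- function(v0) {
    iters <<- iters + 1L
    cfg <- short
    cfg$initial_volume <- v0
    traj <- simulate_niche(cfg, dt = min(0.01, (target_time - config$t_start) / 10))
    utils::tail(traj$observables$V_combined, 1L)
  }
  lo <- 1e-6
  hi <- 10 * config$fate$V_max
  f_hi <- vol_at_target(hi)
  if (f_hi < target_volume) {
    rlang::abort(sprintf("target volume %.4g exceeds the maximum achievable %.4g",
                         target_volume, f_hi),
                 class = "nichegrowth_calibration_error")
  }
  root <- stats::uniroot(function(v) vol_at_target(v) - target_volume,
                         lower = lo, upper = hi,
                         tol = 1e-12 * hi, maxiter = 200L)
  achieved <- vol_at_target(root$root)
  converged <- abs(achieved - target_volume) / target_volume <= tol
  out <- config
  out$initial_volume <- root$root
  structure(list(initial_volume = root$root, achieved_target = achieved,
                 target_volume = target_volume, iterations = iters,
                 converged = converged, config = out),
            class = "niche_calibration")
}

#' @export
print.niche_calibration <- function(x, ...) {
  cat(sprintf("<niche_calibration> V0=%.6g -> %.6g at target (aim %.6g), %d evals, %s\n",
              x$initial_volume, x$achieved_target, x$target_volume, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Time at which a volume series peaks (plateau onset)
#'
#' The plateau is operationalised as the time of the global maximum of the
#' selected volume series (the series rises, then decays as terminal
#' differentiation drains the niche). A series that is still non-decreasing
#' at the end of the trajectory is flagged still-growing and reported at
#' `t_end`.
#'
#' @param trajectory A `niche_trajectory`.
#' @param compartment `"VZ"` (radial glia volume) or `"combined"` (VZ/SVZ).
#' @return One-row tibble: `compartment`, `t_peak` (nearest 0.05 day),
#'   `t_peak_half` (nearest 0.5 day, for coarse comparison),
#'   `still_growing`.
#' @export
plateau_time <- function(trajectory, compartment = c("VZ", "combined")) {
  if (!inherits(trajectory, "niche_trajectory")) abort_usage("not a niche_trajectory")
  compartment <- match.arg(compartment)
  obs <- trajectory$observables
  if (nrow(obs) < 2L) abort_usage("trajectory too short for plateau detection")
  series <- if (compartment == "VZ") obs$V_VZ else obs$V_combined
  i <- which.max(series)
  still <- i == length(series) && !is.unsorted(series)
  t_peak <- obs$time[i]
  tibble::tibble(compartment = compartment,
                 t_peak = round(t_peak / 0.05) * 0.05,
                 t_peak_half = round(t_peak / 0.5) * 0.5,
                 still_growing = still)
}

#' Cumulative neuron production over a time window
#'
#' Difference of the strictly monotone neuron-production counter between the
#' window ends (linear interpolation between grid points).
#'
#' @param trajectory A `niche_trajectory`.
#' @param window Numeric length-2, `c(from, to)` in embryonic days, within
#'   the trajectory span.
#' @return Neuron volume produced in the window (model units), >= 0.
#' @export
cumulative_neuron_output <- function(trajectory, window) {
  if (!inherits(trajectory, "niche_trajectory")) abort_usage("not a niche_trajectory")
  if (length(window) != 2L || window[2L] < window[1L]) {
    abort_usage("window must be c(from, to) with from <= to")
  }
  tt <- trajectory$times
  if (window[1L] < min(tt) - 1e-9 || window[2L] > max(tt) + 1e-9) {
    abort_usage("window must lie within the trajectory span")
  }
  at <- stats::approx(tt, trajectory$observables$cum_neuron_production,
                      xout = window)$y
  max(at[2L] - at[1L], 0)
}

#' Sensitivity of end-of-run volume to the apoptosis rate
#'
#' Re-simulates the configuration with all apoptosis entry rates scaled by
#' each fold and reports the relative deficit of the combined VZ/SVZ volume
#' at `t_end` against the zero-apoptosis run. Under logistic fate control the
#' niche compensates for moderate apoptosis, which is why several-fold
#' elevated cell death barely dents the growth curve.
#'
#' @param config A `niche_config` whose apoptosis block carries the baseline
#'   rates to be scaled (see [apoptosis_measured()]).
#' @param fold_grid Non-negative scale factors.
#' @return Tibble: `fold`, `V_end`, `deficit` (relative to fold 0).
#' @export
apoptosis_sensitivity <- function(config, fold_grid = c(0, 1, 2, 5, 10)) {
  validate_config(config)
  if (any(fold_grid < 0)) abort_usage("folds must be >= 0")
  run_at <- function(fold) {
    cfg <- config
    cfg$apoptosis <- apoptosis_spec(
      delta_RG = config$apoptosis$delta_RG * fold,
      delta_IP = config$apoptosis$delta_IP * fold,
      t_clear = config$apoptosis$t_clear)
    utils::tail(simulate_niche(cfg)$observables$V_combined, 1L)
  }
  v0 <- run_at(0)
  v <- vapply(sort(unique(c(0, fold_grid))), run_at, numeric(1L))
  folds <- sort(unique(c(0, fold_grid)))
  out <- tibble::tibble(fold = folds, V_end = v, deficit = 1 - v / v0)
  out[out$fold %in% fold_grid, ]
}

#' Is a given apoptosis elevation dynamically insignificant?
#'
#' Compares the apoptotic drag on the niche against its growth: simulates the
#' configuration with apoptosis rates scaled by `fold` and with no apoptosis,
#' and forms the ratio of the log-volume deficit to the net log-growth over
#' the run. Apoptosis is called insignificant when that rate ratio is at or
#' below `threshold` (default 10%, a package constant). The absolute
#' end-of-run volume deficit is also reported (see
#' [apoptosis_sensitivity()]).
#'
#' @param config A `niche_config` carrying baseline apoptosis rates.
#' @param fold Elevation factor to assess (default 5, the measured scale).
#' @param threshold Rate-ratio threshold for insignificance.
#' @return List: `rate_ratio`, `deficit`, `insignificant`.
#' @export
apoptosis_insignificance <- function(config, fold = 5, threshold = 0.1) {
  tab <- apoptosis_sensitivity(config, c(0, fold))
  v0_run <- tab$V_end[tab$fold == 0]
  v_run <- tab$V_end[tab$fold == fold]
  start <- config$initial_volume
  rate_ratio <- log(v0_run / v_run) / log(v0_run / start)
  list(rate_ratio = rate_ratio,
       deficit = 1 - v_run / v0_run,
       insignificant = rate_ratio <= threshold)
}

#' Asymptotic growth rate of a multi-stage cycle (Euler-Lotka)
#'
#' For a cycle of first-order (or Erlang) stages with mean durations `d_i`
#' and binary division at the end of the cycle, the long-run exponential
#' growth rate `lambda` solves `prod_i (1 + lambda * d_i / m)^m = 2`. Serves
#' as the closed-form oracle for the unconstrained (p = 1) proliferation
#' limit of the simulator.
#'
#' @param durations Stage mean durations (hours); zero entries are dropped.
#' @param m Erlang sub-stages per stage.
#' @return Growth rate per hour.
#' @export
#' @examples
#' euler_lotka_rate(9.2)  # single stage: 1/9.2
euler_lotka_rate <- function(durations, m = 1L) {
  d <- durations[durations > 0]
  if (!length(d)) abort_usage("need at least one positive duration")
  f <- function(lam) sum(m * log1p(lam * d / m)) - log(2)
  stats::uniroot(f, lower = 1e-12, upper = 10 / min(d), tol = 1e-14)$root
}

#' Simulate and join both genotypes
#'
#' Calibrates the control and mutant configurations to their measured E14.5
#' combined-volume targets (4 and 1 model units by default), simulates both,
#' and returns a long tibble of observables with a `genotype` column.
#'
#' @param control,mutant `niche_config` objects; defaults are
#'   [default_config()] for each genotype.
#' @param calibrate Calibrate initial volumes to `targets` at `target_time`
#'   before simulating (default TRUE).
#' @param targets Length-2 combined-volume targets `c(control, mutant)`.
#' @param target_time Calibration day (default E14.5).
#' @return Tibble of per-time observables for both genotypes.
#' @export
simulate_comparison <- function(control = default_config("control"),
                                mutant = default_config("mutant"),
                                calibrate = TRUE,
                                targets = c(control = 4, mutant = 1),
                                target_time = 14.5) {
  cfgs <- list(control = control, mutant = mutant)
  if (calibrate) {
    cfgs <- purrr::imap(cfgs, function(cfg, nm) {
      calibrate_initial_volume(cfg, targets[[nm]], target_time)$config
    })
  }
  purrr::imap(cfgs, function(cfg, nm) {
    tibble::add_column(simulate_niche(cfg)$observables, genotype = nm, .before = 1L)
  }) |>
    purrr::list_rbind()
}
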