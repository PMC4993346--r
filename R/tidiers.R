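# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated trajectory
#'
#' @param x A `niche_trajectory`.
#' @param ... Unused.
#' @return The per-time observables tibble (one row per time point).
#' @method tidy niche_trajectory
#' @export
tidy.niche_trajectory <- function(x, ...) x$observables

#' One-row summary of a simulated trajectory
#'
#' @param x A `niche_trajectory`.
#' @param ... Unused.
#' @return Tibble with the genotype-level headline numbers: start/end times,
#'   final volumes, total neuron production, VZ peak day.
#' @method glance niche_trajectory
#' @export
glance.niche_trajectory <- function(x, ...) {
  last <- x$observables[nrow(x$observables), ]
  pk <- plateau_time(x, "VZ")
  tibble::tibble(t_start = min(x$times), t_end = max(x$times),
                 K = x$config$fate$K,
                 V_VZ_end = last$V_VZ, V_SVZ_end = last$V_SVZ,
                 V_combined_end = last$V_combined,
                 neurons_total = last$cum_neuron_production,
                 vz_peak_day = pk$t_peak, vz_still_growing = pk$still_growing,
                 config_fingerprint = x$config_fingerprint)
}

#' Tidy a calibration result
#'
#' @param x A `niche_calibration`.
#' @param ... Unused.
#' @return One-row tibble: `initial_volume`, `achieved_target`,
#'   `target_volume`, `iterations`, `converged`.
#' @method tidy niche_calibration
#' @export
tidy.niche_calibration <- function(x, ...) {
  tibble::tibble(initial_volume = x$initial_volume,
                 achieved_target = x$achieved_target,
                 target_volume = x$target_volume,
                 iterations = x$iterations, converged = x$converged)
}
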