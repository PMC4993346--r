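# Exact stochastic simulation (Gillespie SSA on aggregated counts) of the
# same rates as the ODE model. The deterministic equations are the mean-field
# limit of this continuous-time branching process; agreement of the SSA means
# with the ODE trajectory validates that interpretation.

#' Stochastic branching-process simulation of the niche
#'
#' Runs an exact continuous-time Markov simulation of individual cells under
#' the same per-phase transition rates, logistic fate split, apoptosis,
#' clearance and migration as [simulate_niche()]. Each initial cell carries
#' volume `initial_volume / n0`, so observables are directly comparable with
#' the ODE trajectory.
#'
#' @param config A `niche_config` (its `division_yield` is ignored; cells
#'   always divide into two).
#' @param n0 Number of initial cells (>= 100 recommended; the mean-field
#'   match tightens as `1/sqrt(n0)`).
#' @param record_times Days at which to record observables; defaults to ten
#'   points over the configuration window.
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with one row per record time: `time`, `V_VZ`, `V_SVZ`,
#'   `V_combined`, `V_apoptotic`, `cumulative_neurons`,
#'   `cum_neuron_production`.
#' @export
simulate_branching <- function(config, n0 = 10000L, record_times = NULL,
                               seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  P <- build_model(config)
  lay <- P$layout
  if (is.null(record_times)) {
    record_times <- seq(config$t_start, config$t_end, length.out = 10L)
  }
  record_times <- sort(record_times)
  u <- config$initial_volume / n0

  # integer counts from the deterministic initial occupancy (multinomial)
  y0 <- initial_state(config, lay)
  counts <- numeric(lay$n)
  occ <- y0[seq_len(lay$n)] / sum(y0)
  counts[] <- as.numeric(stats::rmultinom(1L, n0, occ))

  # per-cell event rates (per day) and destinations, from the flow matrix:
  # for state i, advance rate = off-diagonal outflow minus apoptosis
  adv_rate <- numeric(lay$n); adv_to <- rep(NA_integer_, lay$n)
  apo_rate <- numeric(lay$n)
  cyc <- c(lay$rg_range, lay$ip_range)
  for (i in cyc) {
    inflows <- P$A[, i]
    to_ap <- inflows[lay$ap]
    apo_rate[i] <- to_ap
    dest <- setdiff(which(inflows > 0), lay$ap)
    if (length(dest) == 1L) {
      adv_to[i] <- dest
      adv_rate[i] <- inflows[dest]
    }
  }
  # mitosis sources advance out of the chain without a fixed destination
  adv_rate[P$ms_from] <- P$ms_rate
  adv_rate[P$ip_ms_from] <- P$ip_ms_rate
  mig_rate <- -P$A[lay$nw, lay$nw] - 0  # only migration drains NW
  clear_rate <- -P$A[lay$ap, lay$ap]
  total_rate_per_cell <- adv_rate + apo_rate
  total_rate_per_cell[lay$nw] <- mig_rate
  total_rate_per_cell[lay$ap] <- clear_rate

  is_ms <- logical(lay$n); is_ms[P$ms_from] <- TRUE
  ms_age_of <- integer(lay$n); ms_age_of[P$ms_from] <- P$ms_age
  is_ip_ms <- logical(lay$n); is_ip_ms[P$ip_ms_from] <- TRUE

  snapshot <- function(t) {
    n_rg <- sum(counts[lay$rg_range]); n_ip <- sum(counts[lay$ip_range])
    tibble::tibble(time = t,
                   V_VZ = u * n_rg,
                   V_SVZ = u * (n_ip + counts[lay$nw]),
                   V_combined = u * (n_rg + n_ip + counts[lay$nw]),
                   V_apoptotic = u * counts[lay$ap],
                   cumulative_neurons = u * (counts[lay$nm] + counts[lay$nw]),
                   cum_neuron_production = u * counts[lay$cn])
  }

  t <- config$t_start
  out <- vector("list", length(record_times))
  rec <- 1L
  active <- seq_len(lay$n)[total_rate_per_cell > 0]
  repeat {
    w <- counts[active] * total_rate_per_cell[active]
    R <- sum(w)
    t_next <- if (R > 0) t + stats::rexp(1L) / R else Inf
    while (rec <= length(record_times) && record_times[rec] <= t_next) {
      out[[rec]] <- snapshot(record_times[rec])
      rec <- rec + 1L
    }
    if (rec > length(record_times) || !is.finite(t_next)) break
    t <- t_next
    i <- active[sample.int(length(active), 1L, prob = w)]
    counts[i] <- counts[i] - 1
    if (i == lay$nw) {
      counts[lay$nm] <- counts[lay$nm] + 1
    } else if (i == lay$ap) {
      counts[lay$cc] <- counts[lay$cc] + 1
    } else if (stats::runif(1L) < apo_rate[i] / total_rate_per_cell[i]) {
      counts[lay$ap] <- counts[lay$ap] + 1
    } else if (is_ip_ms[i]) {
      counts[lay$nw] <- counts[lay$nw] + 2
      counts[lay$cn] <- counts[lay$cn] + 2
    } else if (is_ms[i]) {
      a <- ms_age_of[i]
      if (a == P$K) {
        counts[P$ip_entry] <- counts[P$ip_entry] + 1
        counts[lay$nw] <- counts[lay$nw] + 1
        counts[lay$cn] <- counts[lay$cn] + 1
      } else {
        p <- if (!is.null(P$p_override)) P$p_override else
          clamp01(1 - u * sum(counts[lay$rg_range]) / P$V_max)
        if (stats::runif(1L) < p) {
          counts[P$eP_next[a + 1L]] <- counts[P$eP_next[a + 1L]] + 2
        } else {
          counts[P$eR_next[a + 1L]] <- counts[P$eR_next[a + 1L]] + 1
          counts[lay$nw] <- counts[lay$nw] + 1
          counts[lay$cn] <- counts[lay$cn] + 1
        }
      }
    } else {
      counts[adv_to[i]] <- counts[adv_to[i]] + 1
    }
  }
  purrr::list_rbind(out[!vapply(out, is.null, logical(1L))])
}
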