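# State-space layout for the phase- and mitotic-age-structured population.
#
# Radial glia (RG) are indexed by mitotic age 0..K and cell-cycle phase, with
# the G1 phase split into three pools by prospective division type (G1P for
# Type I, G1R for Type II, G1D for Type III at the age cap). Intermediate
# progenitors (IP) carry a single un-aged G1->S->G2->M pass. Post-mitotic
# neurons wait in the niche (NEURON_WAITING) before migrating out
# (NEURON_MIGRATED). APOPTOTIC holds dying cells until clearance. Two pure
# accumulators close the books: CUM_NEURON (strictly monotone neuron
# production) and CUM_CLEARED (volume removed by clearance).
#
# Column naming is stable: RG_<pool>_a<age>, IP_<phase>, NEURON_WAITING,
# NEURON_MIGRATED, APOPTOTIC, CUM_NEURON, CUM_CLEARED; with Erlang
# sub-staging (m > 1) cycling entries gain a _s<sub> suffix.

RG_POOLS <- c("G1P", "G1R", "G1D", "S", "G2", "M")

state_layout <- function(K, m = 1L) {
  K <- as.integer(K); m <- as.integer(m)
  rg <- expand.grid(sub = seq_len(m), pool = RG_POOLS, age = 0:K,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ip <- expand.grid(sub = seq_len(m), pool = PHASES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  suffix <- function(sub) if (m > 1L) paste0("_s", sub) else ""
  rg_names <- paste0("RG_", rg$pool, "_a", rg$age, suffix(rg$sub))
  ip_names <- paste0("IP_", ip$pool, suffix(ip$sub))
  extras <- c("NEURON_WAITING", "NEURON_MIGRATED", "APOPTOTIC",
              "CUM_NEURON", "CUM_CLEARED")
  names_all <- c(rg_names, ip_names, extras)
  n_rg <- nrow(rg); n_ip <- nrow(ip)

  # index lookup arrays: rg_idx[age+1, pool, sub], ip_idx[phase, sub]
  rg_idx <- array(0L, dim = c(K + 1L, length(RG_POOLS), m),
                  dimnames = list(NULL, RG_POOLS, NULL))
  rg_idx[cbind(rg$age + 1L, match(rg$pool, RG_POOLS), rg$sub)] <- seq_len(n_rg)
  ip_idx <- array(0L, dim = c(length(PHASES), m), dimnames = list(PHASES, NULL))
  ip_idx[cbind(match(ip$pool, PHASES), ip$sub)] <- n_rg + seq_len(n_ip)

  list(K = K, m = m, n = length(names_all), names = names_all,
       rg_idx = rg_idx, ip_idx = ip_idx,
       rg_range = seq_len(n_rg), rg_age = rg$age, rg_pool = rg$pool,
       ip_range = n_rg + seq_len(n_ip), ip_pool = ip$pool,
       nw = n_rg + n_ip + 1L, nm = n_rg + n_ip + 2L, ap = n_rg + n_ip + 3L,
       cn = n_rg + n_ip + 4L, cc = n_rg + n_ip + 5L)
}

# Initial state: all RG volume at `initial_age`, phase occupancy proportional
# to time spent in each phase, G1 split between the G1P and G1R pools by the
# initial proliferative fraction (all G1D at the age cap), uniform across
# Erlang sub-stages.
initial_state <- function(config, layout = NULL) {
  validate_config(config)
  if (is.null(layout)) layout <- state_layout(config$fate$K, config$erlang_m)
  ph <- config$phases
  a0 <- config$initial_age
  K <- layout$K; m <- layout$m
  p0 <- if (!is.null(config$p_override)) config$p_override else
    proliferative_fraction(config$initial_volume, config$fate$V_max)

  if (a0 == K) {
    w <- c(G1P = 0, G1R = 0, G1D = ph$t_G1D, S = ph$t_S, G2 = ph$t_G2, M = ph$t_M)
  } else {
    w <- c(G1P = p0 * ph$t_G1P, G1R = (1 - p0) * ph$t_G1R, G1D = 0,
           S = ph$t_S, G2 = ph$t_G2, M = ph$t_M)
  }
  w <- w / sum(w)
  y <- numeric(layout$n)
  for (pool in RG_POOLS) {
    ids <- layout$rg_idx[a0 + 1L, pool, ]
    y[ids] <- config$initial_volume * w[[pool]] / m
  }
  names(y) <- layout$names
  y
}

#' Convert a state vector or matrix to a tibble
#'
#' @param state A named state vector, or a matrix with one row per time
#'   point and the documented state columns.
#' @return A tibble with one row per state and one column per state entry.
#' @export
state_as_tibble <- function(state) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L,
                                           dimnames = list(NULL, names(state)))
  tibble::as_tibble(as.data.frame(state))
}
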