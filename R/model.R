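# Right-hand side of the population model: first-order phase transitions,
# logistic fate split at mitosis, intermediate-progenitor division,
# apoptosis, clearance and migration.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Proliferative fraction under logistic fate control
#'
#' The share of sub-cap mitoses that are symmetric proliferative (Type I):
#' `p = 1 - V_VZ / V_max`, clamped to `[0, 1]`. As the VZ fills toward its
#' carrying capacity, divisions shift from proliferation to self-renewal.
#'
#' @param V_VZ Current VZ (radial glia) volume, >= 0.
#' @param V_max Carrying capacity, > 0.
#' @return The proliferative fraction in `[0, 1]`; vectorised over `V_VZ`.
#' @export
#' @examples
#' proliferative_fraction(0, 4)    # empty niche -> 1
#' proliferative_fraction(4, 4)    # saturated niche -> 0
proliferative_fraction <- function(V_VZ, V_max) {
  if (!is.numeric(V_max) || any(V_max <= 0)) abort_domain("V_max must be > 0")
  if (any(V_VZ < 0)) abort_domain("V_VZ must be >= 0")
  clamp01(1 - V_VZ / V_max)
}

#' Fate split of mitosis exit flows
#'
#' Distributes the per-age mitosis exit flow over daughter states. For ages
#' `a < K`, a fraction `p` of the flow divides symmetrically (Type I: two
#' radial-glia daughters at age `a + 1`) and the rest asymmetrically
#' self-renews (Type II: one radial glia at age `a + 1` plus one neuron). At
#' the age cap `a = K` every division is terminal (Type III: one intermediate
#' progenitor plus one neuron). Each unit of mother volume yields
#' `division_yield` units of daughter volume (2 = doubling).
#'
#' @param m_exit_flow Numeric vector of mitosis exit flows for ages `0..K`
#'   (length `K + 1`), volume per unit time.
#' @param p Proliferative fraction in `[0, 1]`.
#' @param K Division cap.
#' @param division_yield Daughter volume per unit mother volume (default 2).
#' @return A list with `rg`, a tibble of radial-glia inflows (columns `age`,
#'   `pool`, `inflow`, where `pool` is the destination G1 pool), and scalars
#'   `ip_inflow` and `neuron_inflow`.
#' @export
mitosis_fate_split <- function(m_exit_flow, p, K, division_yield = 2) {
  K <- as.integer(K)
  if (length(m_exit_flow) != K + 1L) {
    rlang::abort("m_exit_flow must have one entry per age 0..K",
                 class = "nichegrowth_state_error")
  }
  if (any(m_exit_flow < 0)) abort_domain("flows must be non-negative")
  if (p < 0 || p > 1) abort_domain("p must lie in [0, 1]")
  half <- division_yield / 2
  rg <- tibble::tibble(age = integer(), pool = character(), inflow = numeric())
  neuron <- 0
  if (K > 0L) {
    a <- 0:(K - 1L)
    f <- m_exit_flow[a + 1L]
    pool_I <- ifelse(a + 1L < K, "G1P", "G1D")
    pool_II <- ifelse(a + 1L < K, "G1R", "G1D")
    rg <- tibble::tibble(
      age = rep(a + 1L, 2L),
      pool = c(pool_I, pool_II),
      inflow = c(division_yield * p * f, half * (1 - p) * f)
    )
    neuron <- half * (1 - p) * sum(f)
  }
  fK <- m_exit_flow[K + 1L]
  list(rg = rg[rg$inflow != 0 | rep(TRUE, nrow(rg)), ],
       ip_inflow = half * fK,
       neuron_inflow = neuron + half * fK)
}

# Precompute the constant part of the dynamics for one configuration: a dense
# flow matrix A holding every state-independent linear flow (phase advances,
# apoptosis entries, clearance, migration, and the *outflow* side of mitosis),
# plus index/rate tables for the state-dependent mitosis destinations.
build_model <- function(config) {
  validate_config(config)
  lay <- state_layout(config$fate$K, config$erlang_m)
  K <- lay$K; m <- lay$m; n <- lay$n
  ph <- config$phases
  A <- matrix(0, n, n)

  dur <- c(G1P = ph$t_G1P, G1R = ph$t_G1R, G1D = ph$t_G1D,
           S = ph$t_S, G2 = ph$t_G2, M = ph$t_M)
  sgm <- c("S", "G2", "M")[dur[c("S", "G2", "M")] > 0]
  phase_of_pool <- c(G1P = "G1", G1R = "G1", G1D = "G1", S = "S", G2 = "G2", M = "M")

  ms_from <- integer(0); ms_rate <- numeric(0); ms_age <- integer(0)

  add_chain <- function(ids, rate_day, next_entry, age_for_mitosis) {
    # ids: substage indices of one phase (length m); flows sub->sub then out
    for (i in seq_len(m)) {
      from <- ids[i]
      A[from, from] <<- A[from, from] - rate_day
      if (i < m) {
        A[ids[i + 1L], from] <<- A[ids[i + 1L], from] + rate_day
      } else if (!is.na(next_entry)) {
        A[next_entry, from] <<- A[next_entry, from] + rate_day
      } else {
        ms_from <<- c(ms_from, from)
        ms_rate <<- c(ms_rate, rate_day)
        ms_age <<- c(ms_age, age_for_mitosis)
      }
    }
  }

  for (a in 0:K) {
    first_sgm_entry <- if (length(sgm)) lay$rg_idx[a + 1L, sgm[1L], 1L] else NA_integer_
    for (pool in c("G1P", "G1R", "G1D")) {
      add_chain(lay$rg_idx[a + 1L, pool, ], 24 * m / dur[[pool]],
                first_sgm_entry, a)
    }
    if (length(sgm)) {
      for (j in seq_along(sgm)) {
        nxt <- if (j < length(sgm)) lay$rg_idx[a + 1L, sgm[j + 1L], 1L] else NA_integer_
        add_chain(lay$rg_idx[a + 1L, sgm[j], ], 24 * m / dur[[sgm[j]]], nxt, a)
      }
    }
  }

  # apoptosis entries from every cycling RG sub-state
  d_rg <- config$apoptosis$delta_RG
  for (pool in RG_POOLS) {
    if (dur[[pool]] <= 0) next
    rate <- 24 * d_rg[[phase_of_pool[[pool]]]]
    if (rate > 0) {
      ids <- as.vector(lay$rg_idx[, pool, ])
      for (from in ids) {
        A[from, from] <- A[from, from] - rate
        A[lay$ap, from] <- A[lay$ap, from] + rate
      }
    }
  }

  # intermediate progenitors: one G1->S->G2->M pass with total time t_IP_cycle
  # apportioned across phases like the Type I radial-glia cycle
  w_ip <- c(G1 = ph$t_G1P, S = ph$t_S, G2 = ph$t_G2, M = ph$t_M)
  d_ip_phase <- config$aux$t_IP_cycle * w_ip / sum(w_ip)
  ip_phases <- PHASES[d_ip_phase > 0]
  ip_entry <- lay$ip_idx[ip_phases[1L], 1L]
  ip_ms_from <- integer(0); ip_ms_rate <- numeric(0)
  for (j in seq_along(ip_phases)) {
    phj <- ip_phases[j]
    ids <- lay$ip_idx[phj, ]
    rate_day <- 24 * m / d_ip_phase[[phj]]
    for (i in seq_len(m)) {
      from <- ids[i]
      A[from, from] <- A[from, from] - rate_day
      if (i < m) {
        A[ids[i + 1L], from] <- A[ids[i + 1L], from] + rate_day
      } else if (j < length(ip_phases)) {
        A[lay$ip_idx[ip_phases[j + 1L], 1L], from] <-
          A[lay$ip_idx[ip_phases[j + 1L], 1L], from] + rate_day
      } else {
        ip_ms_from <- c(ip_ms_from, from)
        ip_ms_rate <- c(ip_ms_rate, rate_day)
      }
    }
    d_ipv <- config$apoptosis$delta_IP[[phj]]
    if (d_ipv > 0) {
      for (from in ids) {
        A[from, from] <- A[from, from] - 24 * d_ipv
        A[lay$ap, from] <- A[lay$ap, from] + 24 * d_ipv
      }
    }
  }

  # migration and clearance
  r_mig <- 24 / config$aux$t_migrate
  A[lay$nw, lay$nw] <- A[lay$nw, lay$nw] - r_mig
  A[lay$nm, lay$nw] <- A[lay$nm, lay$nw] + r_mig
  r_clear <- 24 / config$apoptosis$t_clear
  A[lay$ap, lay$ap] <- A[lay$ap, lay$ap] - r_clear
  A[lay$cc, lay$ap] <- A[lay$cc, lay$ap] + r_clear

  # per-age daughter entry points (first sub-stage of the destination pool)
  eP_next <- eR_next <- integer(K)
  if (K > 0L) {
    for (a in 0:(K - 1L)) {
      eP_next[a + 1L] <- lay$rg_idx[a + 2L, if (a + 1L < K) "G1P" else "G1D", 1L]
      eR_next[a + 1L] <- lay$rg_idx[a + 2L, if (a + 1L < K) "G1R" else "G1D", 1L]
    }
  }

  list(layout = lay, A = A,
       ms_from = ms_from, ms_rate = ms_rate, ms_age = ms_age,
       ip_ms_from = ip_ms_from, ip_ms_rate = ip_ms_rate, ip_entry = ip_entry,
       eP_next = eP_next, eR_next = eR_next,
       V_max = config$fate$V_max, K = K,
       p_override = config$p_override, yield = config$division_yield)
}

# Fast rhs used by the integrator (parms = build_model(config) output).
rhs_core <- function(t, y, P) {
  if (any(!is.finite(y))) abort_numerical("non-finite state encountered")
  lay <- P$layout
  d <- as.vector(P$A %*% y)

  f_src <- P$ms_rate * y[P$ms_from]
  fa <- numeric(P$K + 1L)
  if (length(f_src)) {
    sums <- rowsum(f_src, P$ms_age)
    fa[as.integer(rownames(sums)) + 1L] <- sums[, 1L]
  }
  V_VZ <- sum(y[lay$rg_range])
  p <- if (!is.null(P$p_override)) P$p_override else clamp01(1 - V_VZ / P$V_max)
  half <- P$yield / 2
  neuron_in <- 0
  if (P$K > 0L) {
    f_sub <- fa[seq_len(P$K)]
    d[P$eP_next] <- d[P$eP_next] + P$yield * p * f_sub
    d[P$eR_next] <- d[P$eR_next] + half * (1 - p) * f_sub
    neuron_in <- half * (1 - p) * sum(f_sub)
  }
  fK <- fa[P$K + 1L]
  d[P$ip_entry] <- d[P$ip_entry] + half * fK
  neuron_in <- neuron_in + half * fK

  f_ip <- sum(P$ip_ms_rate * y[P$ip_ms_from])
  neuron_in <- neuron_in + P$yield * f_ip

  d[lay$nw] <- d[lay$nw] + neuron_in
  d[lay$cn] <- d[lay$cn] + neuron_in
  list(d)
}

#' Time derivative of the population state
#'
#' Assembles the full right-hand side of the model at one state: first-order
#' phase exits, the logistic fate split applied to mitosis exit flows,
#' intermediate-progenitor division into two neurons, migration of waiting
#' neurons, apoptosis entries and clearance.
#'
#' @param t Embryonic time (days); the dynamics are autonomous, `t` is
#'   accepted for integrator compatibility.
#' @param state Named state vector in the documented layout (see
#'   [initial_state()] via [simulate_niche()], or build one with
#'   `nichegrowth:::initial_state`).
#' @param config A `niche_config`.
#' @return Named vector of time derivatives (volume units per day).
#' @export
model_rhs <- function(t, state, config) {
  P <- build_model(config)
  if (length(state) != P$layout$n) {
    rlang::abort("state length does not match the configuration's layout",
                 class = "nichegrowth_state_error")
  }
  d <- rhs_core(t, state, P)[[1L]]
  names(d) <- P$layout$names
  d
}

#' Derived observables of a population state
#'
#' @param state A named state vector or a matrix of states (rows = times)
#'   with the documented column layout.
#' @param config The `niche_config` that generated the state (needed for K,
#'   V_max and rates used in the realized fate shares).
#' @return A tibble with one row per state: `V_VZ` (radial glia), `V_SVZ`
#'   (intermediate progenitors plus waiting neurons), `V_combined`,
#'   `V_apoptotic`, `cumulative_neurons` (migrated plus waiting),
#'   `cum_neuron_production` (strictly monotone production counter),
#'   `mean_remaining_divisions` (K minus the volume-weighted mean radial-glia
#'   mitotic age; `NA` when the VZ is empty), phase occupancy fractions of
#'   cycling volume (`frac_G1` ... `frac_M`), the proliferative fraction `p`
#'   and the realized terminal-mitosis share `q_realized`.
#' @export
observables <- function(state, config) {
  P <- build_model(config)
  lay <- P$layout
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L,
                                           dimnames = list(NULL, names(state)))
  if (ncol(state) != lay$n) {
    rlang::abort("state has wrong number of columns for this configuration",
                 class = "nichegrowth_state_error")
  }
  rg <- state[, lay$rg_range, drop = FALSE]
  ip <- state[, lay$ip_range, drop = FALSE]
  V_VZ <- rowSums(rg)
  V_ip <- rowSums(ip)
  nw <- state[, lay$nw]
  V_SVZ <- V_ip + nw
  age_w <- as.vector(rg %*% lay$rg_age)
  mrd <- ifelse(V_VZ > 0, P$K - age_w / V_VZ, NA_real_)

  phase_of <- c(G1P = "G1", G1R = "G1", G1D = "G1", S = "S", G2 = "G2", M = "M")
  cyc <- V_VZ + V_ip
  frac <- sapply(PHASES, function(phz) {
    cols_rg <- lay$rg_range[phase_of[lay$rg_pool] == phz]
    cols_ip <- lay$ip_range[lay$ip_pool == phz]
    tot <- rowSums(state[, c(cols_rg, cols_ip), drop = FALSE])
    ifelse(cyc > 0, tot / cyc, NA_real_)
  })
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1L, dimnames = list(NULL, PHASES))

  p <- if (!is.null(P$p_override)) rep(P$p_override, length(V_VZ)) else
    clamp01(1 - V_VZ / P$V_max)
  # realized share of mitoses occurring at the age cap
  q_realized <- apply(state, 1L, function(y) {
    f <- P$ms_rate * y[P$ms_from]
    tot <- sum(f)
    if (tot > 0) sum(f[P$ms_age == P$K]) / tot else NA_real_
  })

  tibble::tibble(
    V_VZ = unname(V_VZ), V_SVZ = unname(V_SVZ),
    V_combined = unname(V_VZ + V_SVZ), V_IP = unname(V_ip),
    V_apoptotic = unname(state[, lay$ap]),
    cumulative_neurons = unname(state[, lay$nm] + nw),
    cum_neuron_production = unname(state[, lay$cn]),
    mean_remaining_divisions = unname(mrd),
    frac_G1 = unname(frac[, "G1"]), frac_S = unname(frac[, "S"]),
    frac_G2 = unname(frac[, "G2"]), frac_M = unname(frac[, "M"]),
    p = unname(p), q_realized = unname(q_realized)
  )
}
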