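# Synthetic specimens: virtual sectioned brains with known true volumes,
# densities and marker fractions, sampled with the study's stereology
# designs. These stand in for the animal data so the whole measurement
# pipeline (sampling -> estimation -> fold-change summary) can be tested
# end to end.

#' Specify a synthetic specimen
#'
#' True quantities can be tied to a simulated trajectory (volume from the
#' combined VZ/SVZ at `age` scaled by `volume_scale`, apoptotic fraction
#' from the apoptotic compartment, marker fractions from the phase
#' occupancies) or given directly via `true_volume` / `apoptotic_fraction`.
#'
#' @param genotype `"control"` or `"mutant"` (label only).
#' @param age Embryonic day of the virtual specimen.
#' @param trajectory Optional `niche_trajectory` to read truths from.
#' @param true_volume True region volume (um^3); required when no
#'   trajectory is given.
#' @param volume_scale um^3 per model volume unit (default 8e7, placing the
#'   control E14.5 combined VZ/SVZ near 3.2e8 um^3).
#' @param true_cell_density Cells per um^3 (default 1e-3, one cell per
#'   1000 um^3).
#' @param apoptotic_fraction Fraction of cells in the apoptotic state.
#' @param pulse BrdU pulse length (hours) for the marker forward model.
#' @param chase,inm_delay CldU chase and nuclear-migration delay (hours).
#' @param tbr2_density Tbr2-positive cells per um^3.
#' @param seed Integer seed; all sampling for this specimen flows from it.
#' @return A `niche_specimen_spec`.
#' @export
specimen_spec <- function(genotype = c("control", "mutant"), age = 14.5,
                          trajectory = NULL, true_volume = NULL,
                          volume_scale = 8e7, true_cell_density = 1e-3,
                          apoptotic_fraction = 0.002, pulse = 0.5,
                          chase = 2.5, inm_delay = 1, tbr2_density = 2e-4,
                          seed = 1L) {
  genotype <- match.arg(genotype)
  markers <- NULL
  inm_true <- NA_real_
  if (!is.null(trajectory)) {
    if (!inherits(trajectory, "niche_trajectory")) abort_usage("not a niche_trajectory")
    obs <- trajectory$observables
    at <- function(col) stats::approx(obs$time, obs[[col]], age)$y
    true_volume <- at("V_combined") * volume_scale
    va <- at("V_apoptotic")
    apoptotic_fraction <- va / (va + at("V_combined"))
    cfg <- trajectory$config
    fr <- c(G1 = at("frac_G1"), S = at("frac_S"),
            G2 = at("frac_G2"), M = at("frac_M"))
    # phase fractions are shares of cycling volume (VZ + IP); rescale them to
    # shares of the whole niche before feeding the marker forward model
    share <- (at("V_VZ") + at("V_IP")) / at("V_combined")
    markers <- marker_fractions(cfg, fr * share, pulse = pulse)
    inm_true <- inm_ventricle_fraction(cfg$phases$t_S, chase, inm_delay)
  }
  if (is.null(true_volume)) abort_usage("need a trajectory or a true_volume")
  if (true_volume < 0 || true_cell_density < 0) abort_validation("volume and density must be >= 0")
  if (apoptotic_fraction < 0 || apoptotic_fraction > 1) {
    abort_validation("apoptotic_fraction must lie in [0, 1]")
  }
  structure(list(genotype = genotype, age = age, true_volume = true_volume,
                 true_cell_density = true_cell_density,
                 apoptotic_fraction = apoptotic_fraction,
                 markers = markers, inm_true = inm_true,
                 pulse = pulse, chase = chase, inm_delay = inm_delay,
                 tbr2_density = tbr2_density, seed = as.integer(seed)),
            class = "niche_specimen_spec")
}

#' Generate a synthetic specimen's measurements
#'
#' Virtually sections an ellipsoid of the specimen's true volume and draws
#' every readout with Poisson sampling noise: Cavalieri point counts per
#' section (mean = sectioned area over grid area-per-point), fractionator
#' dissector counts per site (mean = density x counting-frame volume),
#' caspase-positive counts thinned by the apoptotic fraction, binomially
#' scored marker fractions, CldU-at-ventricle counts, and a Tbr2 total.
#' Deterministic given the spec's seed.
#'
#' @param spec A [specimen_spec()].
#' @param cavalieri A [cavalieri_design()].
#' @param fractionator A [fractionator_design()].
#' @param n_scored Cells scored per marker for the marker fractions.
#' @param n_labeled CldU-labelled cells scored for the ventricle fraction.
#' @return A `niche_specimen`: list with `cavalieri` (tibble
#'   `section_index, count`), `fractionator` (tibble `section_index,
#'   site_index, count, caspase_count`), `markers` (tibble `marker,
#'   positive, scored, fraction`), `cldu` (list `at_ventricle, labeled,
#'   fraction`), `tbr2_total`, `spec`, and `degenerate` flag.
#' @export
generate_specimen <- function(spec,
                              cavalieri = stereology_preset("cavalieri_vzsvz"),
                              fractionator = stereology_preset("fractionator_caspase3"),
                              n_scored = 500L, n_labeled = 200L) {
  if (!inherits(spec, "niche_specimen_spec")) abort_usage("not a niche_specimen_spec")
  set.seed(spec$seed)
  degenerate <- spec$true_volume <= 0
  semi <- ellipsoid_semiaxes(max(spec$true_volume, 0))

  section_areas <- function(thickness, interval) {
    period <- thickness * interval
    cc <- semi[3L]
    if (degenerate) return(numeric(0))
    z0 <- stats::runif(1L, 0, period)
    z <- seq(z0 - period * ceiling((z0 + cc) / period), cc, by = period)
    z <- z[z >= -cc & z <= cc]
    pi * semi[1L] * semi[2L] * pmax(1 - (z / cc)^2, 0)
  }

  areas <- section_areas(cavalieri$section_thickness, cavalieri$section_interval)
  cav_counts <- if (length(areas)) {
    stats::rpois(length(areas), areas / cavalieri$grid_spacing^2)
  } else integer(0)
  cav <- tibble::tibble(section_index = seq_along(cav_counts), count = cav_counts)

  areas_f <- section_areas(fractionator$section_thickness,
                           fractionator$section_interval)
  frame_vol <- prod(fractionator$frame) * fractionator$dissector_height
  frac_rows <- purrr::imap(areas_f, function(ar, si) {
    n_sites <- stats::rpois(1L, ar / prod(fractionator$grid))
    if (n_sites == 0L) return(NULL)
    tibble::tibble(
      section_index = si, site_index = seq_len(n_sites),
      count = stats::rpois(n_sites, spec$true_cell_density * frame_vol),
      caspase_count = stats::rpois(n_sites, spec$true_cell_density *
                                     spec$apoptotic_fraction * frame_vol))
  })
  frac <- purrr::list_rbind(purrr::compact(frac_rows))
  if (nrow(frac) == 0L) {
    frac <- tibble::tibble(section_index = integer(), site_index = integer(),
                           count = integer(), caspase_count = integer())
  }

  markers <- NULL
  if (!is.null(spec$markers)) {
    pos <- stats::rbinom(3L, n_scored, unlist(spec$markers))
    markers <- tibble::tibble(marker = names(spec$markers), positive = pos,
                              scored = n_scored, fraction = pos / n_scored)
  }
  cldu <- NULL
  if (is.finite(spec$inm_true)) {
    atv <- stats::rbinom(1L, n_labeled, spec$inm_true)
    cldu <- list(at_ventricle = atv, labeled = n_labeled,
                 fraction = atv / n_labeled)
  }
  tbr2_total <- stats::rpois(1L, spec$tbr2_density * spec$true_volume)

  structure(list(cavalieri = cav, fractionator = frac, markers = markers,
                 cldu = cldu, tbr2_total = tbr2_total, spec = spec,
                 degenerate = degenerate),
            class = "niche_specimen")
}

#' Forward model of proliferation-marker fractions
#'
#' Maps cell-cycle phase occupancies to the three marker readouts: BrdU (a
#' short pulse labels cells in S, plus cells entering S during the pulse,
#' approximated by `pulse / Tc` of the G1 share with `Tc` the Type I transit
#' time), Ki67 (all cycling cells), and pH3 (cells in M).
#'
#' @param config A `niche_config` (supplies the transit time).
#' @param phase_fractions Named shares of total niche volume in `G1, S, G2,
#'   M`; their sum (the cycling share) must be `<= 1`.
#' @param pulse Pulse duration in hours.
#' @return Named list `BrdU`, `Ki67`, `pH3` (fractions of total volume).
#' @export
#' @examples
#' marker_fractions(default_config(), c(G1 = 0, S = 1, G2 = 0, M = 0), 0)
marker_fractions <- function(config, phase_fractions, pulse = 0.5) {
  validate_config(config)
  f <- phase_fractions[PHASES]
  if (any(is.na(f)) || any(f < 0)) abort_domain("phase shares must be named, non-negative")
  cycling <- sum(f)
  if (cycling > 1 + 1e-9) abort_domain("cycling shares must sum to <= 1")
  if (pulse < 0) abort_domain("pulse must be >= 0")
  Tc <- transit_time(config, "I")
  brdu <- min(f[["S"]] + pulse / Tc * f[["G1"]], cycling)
  list(BrdU = unname(brdu), Ki67 = unname(cycling), pH3 = unname(f[["M"]]))
}

#' Expected CldU-at-ventricle fraction under interkinetic nuclear migration
#'
#' A pulse labels cells in S; after a chase, the labelled cells that have
#' completed S and finished the apical migration delay are found at the
#' ventricular surface. With label positions uniform across S, that fraction
#' is `clamp((chase - inm_delay) / t_S, 0, 1)`; a longer S phase lowers it.
#'
#' @param t_S S-phase duration (hours).
#' @param chase Chase time (hours), >= 0.
#' @param inm_delay Apical-migration delay (hours) after S exit.
#' @return Expected fraction in `[0, 1]`.
#' @export
#' @examples
#' inm_ventricle_fraction(4, 2.5, 1)    # control: 0.375
#' inm_ventricle_fraction(5, 2.5, 1)    # elongated S: 0.3
inm_ventricle_fraction <- function(t_S, chase, inm_delay = 1) {
  if (t_S <= 0 || inm_delay < 0) abort_domain("durations must be positive")
  if (chase < 0) abort_domain("chase must be >= 0")
  clamp01((chase - inm_delay) / t_S)
}

#' Fold-change summary across specimen groups
#'
#' Computes per-specimen readouts (Cavalieri volume, total cells, apoptotic
#' density = caspase-positive total over estimated volume, Tbr2 total),
#' then group fold changes with bootstrap percentile intervals. Volume and
#' Tbr2 folds are reported control/mutant, apoptosis mutant/control.
#'
#' @param control,mutant Lists of `niche_specimen` objects (>= 2 each for
#'   intervals).
#' @param cavalieri,fractionator The designs the specimens were sampled
#'   with.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @param conf Interval coverage (default 0.95).
#' @return Tibble: `readout`, `direction`, `fold`, `lo`, `hi`,
#'   `interval_available`.
#' @export
fold_change_summary <- function(control, mutant,
                                cavalieri = stereology_preset("cavalieri_vzsvz"),
                                fractionator = stereology_preset("fractionator_caspase3"),
                                n_boot = 2000L, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  readout_row <- function(sp) {
    stopifnot(inherits(sp, "niche_specimen"))
    vol <- if (nrow(sp$cavalieri)) cavalieri_volume(sp$cavalieri$count, cavalieri) else 0
    cells <- if (nrow(sp$fractionator)) fractionator_count(sp$fractionator$count, fractionator) else 0
    casp <- if (nrow(sp$fractionator)) fractionator_count(sp$fractionator$caspase_count, fractionator) else 0
    tibble::tibble(volume = vol, cells = cells,
                   apoptosis_density = if (vol > 0) casp / vol else NA_real_,
                   tbr2_total = sp$tbr2_total)
  }
  ctab <- purrr::list_rbind(purrr::map(control, readout_row))
  mtab <- purrr::list_rbind(purrr::map(mutant, readout_row))
  readouts <- tibble::tribble(
    ~readout, ~direction,
    "volume", "control/mutant",
    "cells", "control/mutant",
    "apoptosis_density", "mutant/control",
    "tbr2_total", "control/mutant"
  )
  both_multi <- nrow(ctab) >= 2L && nrow(mtab) >= 2L
  summarise_one <- function(readout, direction) {
    fold_of <- function(ci, mi) {
      cm <- mean(ctab[[readout]][ci], na.rm = TRUE)
      mm <- mean(mtab[[readout]][mi], na.rm = TRUE)
      if (direction == "control/mutant") cm / mm else mm / cm
    }
    fold <- fold_of(seq_len(nrow(ctab)), seq_len(nrow(mtab)))
    lo <- hi <- NA_real_
    if (both_multi) {
      boots <- vapply(seq_len(n_boot), function(i) {
        fold_of(sample.int(nrow(ctab), replace = TRUE),
                sample.int(nrow(mtab), replace = TRUE))
      }, numeric(1L))
      qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            na.rm = TRUE, names = FALSE)
      lo <- qs[1L]; hi <- qs[2L]
    }
    tibble::tibble(readout = readout, direction = direction, fold = fold,
                   lo = lo, hi = hi, interval_available = both_multi)
  }
  purrr::list_rbind(purrr::pmap(readouts, summarise_one))
}
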