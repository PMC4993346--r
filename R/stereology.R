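# Design-based stereology: Cavalieri volume estimation and optical
# fractionator cell counting, with the sampling designs used to quantify the
# embryonic VZ/SVZ, and a virtual sectioning sampler for unbiasedness checks
# on synthetic solids.

#' Cavalieri sampling design
#'
#' @param grid_spacing Point-grid spacing (um); area per point =
#'   `grid_spacing^2`.
#' @param section_thickness Section thickness (um).
#' @param section_interval Evaluate one of every `section_interval` sections.
#' @return A `cavalieri_design`.
#' @export
#' @examples
#' cavalieri_design()  # grid 30 um, 50 um sections, 1-in-5 sampling
cavalieri_design <- function(grid_spacing = 30, section_thickness = 50,
                             section_interval = 5L) {
  if (grid_spacing <= 0 || section_thickness <= 0 || section_interval < 1) {
    abort_validation("Cavalieri design parameters must be positive")
  }
  structure(list(grid_spacing = grid_spacing,
                 section_thickness = section_thickness,
                 section_interval = as.integer(section_interval)),
            class = "cavalieri_design")
}

#' Optical-fractionator sampling design
#'
#' Defaults are the VZ/SVZ caspase-3 design: 50 x 50 um counting frame on a
#' 153.9 x 162.5 um sampling grid, 20 um dissector in 50 um sections, one of
#' every five sections (`section_interval = 10` for the NeuN design).
#'
#' @param frame Counting-frame width and height (um), length 2.
#' @param grid Sampling-grid step in x and y (um), length 2.
#' @param dissector_height Optical dissector height (um), `<=`
#'   `section_thickness`.
#' @param section_thickness Section thickness (um).
#' @param section_interval Evaluate one of every `section_interval` sections.
#' @return A `fractionator_design`.
#' @export
fractionator_design <- function(frame = c(50, 50), grid = c(153.9, 162.5),
                                dissector_height = 20, section_thickness = 50,
                                section_interval = 5L) {
  if (any(frame <= 0) || any(grid <= 0) || dissector_height <= 0 ||
      section_thickness <= 0 || section_interval < 1) {
    abort_validation("fractionator design parameters must be positive")
  }
  if (prod(frame) > prod(grid)) {
    abort_validation("counting-frame area must not exceed sampling-grid area")
  }
  if (dissector_height > section_thickness) {
    abort_validation("dissector height must not exceed section thickness")
  }
  structure(list(frame = frame, grid = grid,
                 dissector_height = dissector_height,
                 section_thickness = section_thickness,
                 section_interval = as.integer(section_interval)),
            class = "fractionator_design")
}

#' Study sampling-design presets
#'
#' @param name `"cavalieri_vzsvz"` (E14.5/E17.5 VZ/SVZ and dentate, 1-in-5),
#'   `"cavalieri_p0_dentate"` (1-in-10), `"fractionator_caspase3"` (1-in-5)
#'   or `"fractionator_neun"` (1-in-10).
#' @return The corresponding design object.
#' @export
stereology_preset <- function(name = c("cavalieri_vzsvz", "cavalieri_p0_dentate",
                                       "fractionator_caspase3",
                                       "fractionator_neun")) {
  name <- match.arg(name)
  switch(name,
    cavalieri_vzsvz = cavalieri_design(section_interval = 5L),
    cavalieri_p0_dentate = cavalieri_design(section_interval = 10L),
    fractionator_caspase3 = fractionator_design(section_interval = 5L),
    fractionator_neun = fractionator_design(section_interval = 10L)
  )
}

#' Cavalieri volume estimate
#'
#' `V_hat = sum(P_i) * grid_spacing^2 * section_thickness * section_interval`
#' for point counts `P_i` on the sampled sections.
#'
#' @param point_counts Non-negative integer point counts, one per sampled
#'   section.
#' @param design A [cavalieri_design()].
#' @return Estimated volume in um^3.
#' @export
#' @examples
#' cavalieri_volume(c(40, 35, 25), cavalieri_design())  # 2.25e7 um^3
cavalieri_volume <- function(point_counts, design = cavalieri_design()) {
  if (!inherits(design, "cavalieri_design")) abort_usage("not a cavalieri_design")
  if (length(point_counts) == 0L) abort_usage("point_counts must be non-empty")
  if (any(point_counts < 0) || any(point_counts != round(point_counts))) {
    abort_validation("point counts must be non-negative integers")
  }
  sum(point_counts) * design$grid_spacing^2 * design$section_thickness *
    design$section_interval
}

#' Optical-fractionator total-count estimate
#'
#' `N_hat = sum(Q_i) * section_interval * (grid_area / frame_area) *
#' (section_thickness / dissector_height)`: the dissector counts `Q_i`
#' scaled by the inverse section, area and thickness sampling fractions.
#'
#' @param cell_counts Non-negative integer dissector counts, one per sampled
#'   site.
#' @param design A [fractionator_design()].
#' @return Estimated total cell number.
#' @export
fractionator_count <- function(cell_counts, design = fractionator_design()) {
  if (!inherits(design, "fractionator_design")) abort_usage("not a fractionator_design")
  if (length(cell_counts) == 0L) abort_usage("cell_counts must be non-empty")
  if (any(cell_counts < 0) || any(cell_counts != round(cell_counts))) {
    abort_validation("cell counts must be non-negative integers")
  }
  sum(cell_counts) * design$section_interval *
    prod(design$grid) / prod(design$frame) *
    design$section_thickness / design$dissector_height
}

#' Gundersen coefficient of error for Cavalieri point counts
#'
#' Classic systematic-sampling CE: `CE = sqrt(noise + var_SURS) / sum(P)`
#' with `noise = 0.0724 * shape_factor * sqrt(n * sum(P))` and
#' `var_SURS = (3A - 4B + C) / 12` from the count autocovariances. Different
#' stereology packages use slightly different smoothness variants; this is
#' the classic one.
#'
#' @param point_counts Per-section point counts, in section order.
#' @param shape_factor Object shape factor (boundary/sqrt(area); 4 for the
#'   study's software settings).
#' @return Estimated coefficient of error of the volume estimate.
#' @export
gundersen_ce <- function(point_counts, shape_factor = 4) {
  p <- as.numeric(point_counts)
  n <- length(p)
  if (n < 3L) abort_usage("need at least 3 sections for the CE estimate")
  A <- sum(p * p)
  B <- sum(p[-n] * p[-1L])
  C <- sum(p[seq_len(n - 2L)] * p[-(1:2)])
  var_surs <- (3 * A - 4 * B + C) / 12
  noise <- 0.0724 * shape_factor * sqrt(n * sum(p))
  sqrt(pmax(noise + var_surs, 0)) / sum(p)
}

# --- virtual sectioning of an ellipsoid ------------------------------------

#' Semi-axes of an ellipsoid with given volume
#'
#' @param volume Target volume (um^3).
#' @param aspect Relative semi-axis proportions (x, y, z).
#' @return Numeric length-3 semi-axes (um).
#' @export
ellipsoid_semiaxes <- function(volume, aspect = c(1, 0.8, 0.6)) {
  if (volume < 0) abort_domain("volume must be >= 0")
  s <- (volume / (4 / 3 * pi * prod(aspect)))^(1 / 3)
  s * aspect
}

#' Virtually section an ellipsoid and count Cavalieri grid points
#'
#' Emulates the physical sampling: sections of the design thickness are cut
#' along z, one in every `section_interval` is sampled with a uniformly
#' random stack offset, and a square point grid with a uniformly random
#' translation is overlaid on each sampled section face; points falling
#' inside the elliptical cross-section are counted exactly (lattice
#' counting, no Monte Carlo within a section). Under this systematic
#' uniform-random design the Cavalieri estimator is unbiased for the true
#' ellipsoid volume.
#'
#' @param semi_axes Ellipsoid semi-axes (um), length 3.
#' @param design A [cavalieri_design()].
#' @return Integer vector of point counts per sampled section (possibly all
#'   zero for a degenerate solid).
#' @export
sample_cavalieri_counts <- function(semi_axes, design = cavalieri_design()) {
  a <- semi_axes[1L]; b <- semi_axes[2L]; cc <- semi_axes[3L]
  s <- design$grid_spacing
  period <- design$section_thickness * design$section_interval
  z0 <- stats::runif(1L, 0, period)
  z <- seq(z0 - period * ceiling((z0 + cc) / period), cc, by = period)
  z <- z[z >= -cc & z <= cc]
  if (!length(z)) return(0L)
  u <- stats::runif(1L, 0, s); v <- stats::runif(1L, 0, s)
  counts <- vapply(z, function(zi) {
    f <- 1 - (zi / cc)^2
    if (f <= 0) return(0L)
    A <- a * sqrt(f); B <- b * sqrt(f)
    x <- seq(u - s * ceiling((u + A) / s), A, by = s)
    x <- x[x >= -A & x <= A]
    if (!length(x)) return(0L)
    ylim <- B * sqrt(pmax(1 - (x / A)^2, 0))
    sum(pmax(floor((ylim - v) / s) - ceiling((-ylim - v) / s) + 1, 0))
  }, numeric(1L))
  as.integer(counts)
}
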