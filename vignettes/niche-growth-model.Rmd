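---
title: "Modelling compensatory growth of the embryonic forebrain stem-cell niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling compensatory growth of the embryonic forebrain stem-cell niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichegrowth)
```

## The model

The embryonic mouse forebrain grows by expansion of radial glia in the
ventricular/subventricular zone (VZ/SVZ). `nichegrowth` tracks the *volume*
of cells indexed by compartment, cell-cycle phase, and mitotic age, as a
system of ordinary differential equations:

* **Radial glia (RG)** cycle through G1 → S → G2 → M. Each age class
  `a = 0..K` records how many divisions the lineage has undergone. G1 is
  split into three pools by the division type the cell is headed for:
  `t_G1P` (symmetric proliferative, Type I), `t_G1R` (asymmetric
  self-renewing, Type II), and `t_G1D` (terminal, Type III). The
  population-average G1 duration is then the mixture
  `t_G1 = p·t_G1P + (1 − p − q)·t_G1R + q·t_G1D`, exposed by
  `effective_g1_time()`; `q` is not a free control but the realized share
  of mitoses occurring at the age cap.
* **Fate at mitosis.** For ages below the cap, a fraction
  `p = 1 − V_VZ / V_max` (clamped to `[0, 1]`) of mitoses are Type I (two
  RG daughters at age `a + 1`); the rest are Type II (one RG daughter plus
  one neuron). At the cap `a = K` every division is Type III: one
  intermediate progenitor plus one neuron. This is logistic fate control:
  as the niche fills toward its carrying capacity `V_max`, proliferation
  gives way to self-renewal, and the division cap drives terminal
  differentiation.
* **Intermediate progenitors (IP)** make a single G1→S→G2→M pass
  (`t_IP_cycle`) and divide into two migratory neurons. Newborn neurons
  wait in the niche (`NEURON_WAITING`, mean residence `t_migrate`) before
  migrating out; cumulative production is tracked by a strictly monotone
  counter.
* **Apoptosis** enters from any cycling phase at per-hour rates and is
  cleared with mean residence `t_clear`.

Stage transitions are first order (exponential stage times), matching a
rate parameterisation by mean transit times. Because exponential stages
make the realized doubling time shorter than the summed means, an Erlang
sub-staging option (`erlang_m`) is available to approximate fixed
durations; every default analysis uses `erlang_m = 1`. Each mitosis
converts one unit of mother volume into two units of daughter volume, so
volume doubling tracks cell-count doubling at fixed cell volume; the
internal `division_yield` switch (set to 1) makes divisions
volume-conserving, which is how the bookkeeping tests express closed-system
conservation.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `t_G1P`, `t_S`, `t_G2`, `t_M` | 3.1, 4.0, 1.6, 0.5 | h | fixed by two constraints: Type I transit 9.2 h and S+G2 = 5.6 h (so a 25% S/G2 elongation adds 1.4 h) |
| `t_G1R`, `t_G1D` | 9.3, 13.0 | h | G1 lengthens toward differentiation |
| `K` | 5 (control), 6 (mutant) | divisions | division budget at E13.5 |
| `V_max` | 4.0 | model units | abstract volume scale; calibration puts the control combined VZ/SVZ at 4 units and the mutant at 1 unit at E14.5, encoding the measured 4-fold ratio |
| `t_IP_cycle` | 14 | h | transit-amplifying single pass |
| `t_migrate` | 24 | h | newborn neurons clear the proliferative zones on a roughly one-day timescale |
| `unit_cell_volume` | 1000 | µm³ | ~10 µm progenitor soma; reporting-layer conversion only |
| `t_clear` | 2 | h | conservatively rapid clearance of apoptotic cells |
| apoptosis baseline | 5e-4 | /h/phase | puts apoptotic occupancy near 0.1% of the niche under 2 h clearance, matching the rarity of cleaved-caspase-3⁺ cells |

The `CCNA2`-null genotype is a *transformation*, not a separate
parameter set: `apply_genotype()` multiplies `t_S` and `t_G2` by 1.25
(the S-phase cyclin is lost, so the elongation is isolated to S/G2),
adds one to `K`, and optionally scales apoptosis. That takes the Type I
transit from 9.2 h to 10.6 h and gives mutant radial glia six divisions —
the developmental-delay hypothesis in mechanistic form.

```{r genotype}
ctrl <- default_config("control")
mut  <- apply_genotype(ctrl, genotype_modifier())
c(control = transit_time(ctrl, "I"), mutant = transit_time(mut, "I"))
```

## Simulation, calibration, readouts

`simulate_niche()` integrates with `deSolve::lsoda` (rtol 1e-8, atol
1e-10) and samples dense output on a 0.01-day grid; the system is small
(≈ 45–51 states at the defaults) and non-stiff, and halving the tolerances
moves E17.5 volumes by less than 1e-6 relative. The initial state puts all
RG volume at `initial_age` (0, so `K` divisions remain), with phase
occupancy proportional to time spent in each phase and the G1 volume split
between the proliferative and self-renewal pools by the initial value of
`p`.

`calibrate_initial_volume()` root-finds the E13.5 initial volume so the
simulated combined volume at E14.5 hits a measured target; the map is
monotone, so bracketed root-finding over `[1e-6, 10·V_max]` is reliable.
Both genotypes start at E13.5 (the mutant with `K = 6` and age 0); only
the volume-ratio at E14.5 is printed by the study, so targets are in
relative units (4 and 1), with absolute-unit conversion left to the
reporting layer.

"Plateau" is not operationalised in the source narrative, so
`plateau_time()` uses the global maximum of the volume series — the VZ
rises, then decays as terminal differentiation drains it — with a
`still_growing` flag for monotone series, reported at 0.05-day resolution
plus a convenience half-day rounding. Under the defaults the control VZ
peaks at E15.0 and the mutant peaks later, within half a day of E15.5;
mutant cumulative neuron output trails the control throughout
E14.5–E17.5, and the volume gap at E17.5 is far smaller than at E14.5 —
compensatory growth via logistic feedback.

Apoptosis sensitivity: `apoptosis_sensitivity()` reports the end-of-run
combined-volume deficit against a zero-apoptosis run across a fold grid.
`apoptosis_insignificance()` compares the log-volume deficit *rate* to the
net growth rate, following the claim that the apoptosis rate is
insignificant *relative to the growth rate*; the 10% threshold is a
package constant. At the measured-scale preset (5-fold elevation) the rate
ratio is well under that threshold while the absolute deficit is an order
of magnitude short of what a lag-phase explanation of the 4-fold E14.5
deficit would require — both quantities are computed in the test suite.

## Hypothesis comparison

`evaluate_hypotheses()` implements an *argument*, not a fit: the candidate
growth families (logistic, rapid cycle, prolonged lag, linear fixed pool,
delayed logistic) are canonical closed forms, and each rejection is an
executable boolean check with its reason recorded — a faster cycle would
require the mutant niche to be larger at E14.5, not 4-fold smaller; the
measured apoptosis elevation is too small to produce a lag phase; linear
fixed-pool growth reaching E17.5 parity from a 4-fold deficit would need
apoptosis comparable to proliferation or a single-cell-type niche. The
delayed-logistic defaults are principled: with shared `r = log(5)`/day and
`V0 = V_max/16`, a one-day shift reproduces the 4-fold E14.5 ratio
exactly and E17.5 parity within the ±25% "not significantly different"
band. With default constraints exactly one family survives.

## Stereology

`cavalieri_volume()` and `fractionator_count()` implement the standard
design-based estimators with the study's sampling presets (30 µm point
grid, 50 µm sections, 1-in-5 or 1-in-10 section sampling; 50×50 µm frame
on a 153.9 × 162.5 µm grid with a 20 µm dissector). The virtual sampler
sections an ellipsoid with uniformly random stack offset and grid
translation and counts lattice points exactly, which makes the Cavalieri
estimator unbiased by construction of the design — verified by Monte Carlo
(10⁴ placements, relative bias < 1%). Counting-frame edge rules and guard
zones are properties of the physical rig the virtual sampler does not need
to emulate at the object level: sites are Poisson-thinned by expected
content, which preserves exactly the first moment the estimators invert.
The classic Gundersen CE (shape factor 4) is included; commercial software
implements several smoothness variants, so only the classic form is
offered.

## Synthetic specimens

`generate_specimen()` draws every readout with Poisson noise (the natural
model for design-based sampling of sparse objects; an overdispersed
variant can be layered on by the user): per-section point counts, per-site
dissector counts, caspase counts thinned by the apoptotic fraction,
binomially scored marker fractions (BrdU = S-share plus a
`pulse/Tc`-weighted G1 adjacency term; Ki67 = cycling share; pH3 =
M-share), a CldU-at-ventricle fraction
`clamp((chase − inm_delay)/t_S, 0, 1)` (with `inm_delay = 1` h, chosen so
the control fraction at the study's 2.5 h chase is materially nonzero —
0.375 vs 0.30 after 25% S elongation), and a Tbr2 total generated as
density × niche volume so per-frame counts match between genotypes while
volume-normalised totals differ. All randomness flows through one seed per
specimen; `volume_scale = 8e7` µm³/unit places the control E14.5 combined
VZ/SVZ near 3.2e8 µm³.

What the generator emulates — and does not: it reproduces the *statistical
structure* the estimators assume (systematic uniform sampling, Poisson
counts, known truths), which is exactly what is needed to verify
unbiasedness and end-to-end fold-change recovery (the injected 4-fold
volume ratio and 5-fold apoptosis elevation are recovered within bootstrap
intervals at n = 10 specimens per group). It does not emulate staining
artifacts, section deformation, anisotropy, or between-animal variance
beyond sampling noise, so passing tests validate the pipeline, not the
biology of any particular mouse.

## Numerical and design choices

* Zero values of `t_S`, `t_G2` or `t_M` collapse the phase out of the
  chain, enabling the degenerate single-stage configuration whose growth
  is exactly `exp(t/9.2 h)` — an analytic anchor for the integrator.
* The unconstrained (`p ≡ 1`) growth rate is checked against the
  Euler–Lotka root of `∏(1 + λ t_i) = 2` to 1e-3 relative.
* The mean-field interpretation is validated by an exact Gillespie
  branching simulation of the same rates: 10⁴ initial cells over a
  half-day horizon, five replicates, means within three Monte-Carlo
  standard deviations of the ODE (the residual offset scales as `1/n₀`,
  as expected for a nonlinear mean-field correction).
* Monte-Carlo problem sizes used by the suite: 10⁴ Cavalieri placements,
  4×10³ fractionator specimens, 10³–2×10³ bootstrap resamples — sizes at
  which the standard error of each check sits an order of magnitude below
  its tolerance.
* Tiny integrator negatives (> −1e-8) are clamped to zero for reporting;
  anything worse raises a typed numerical error rather than propagating.

## Limitations

No spatial structure, no single-cell lineage tracking, no cortical-plate
volume dynamics (cumulative neuron output is reported instead), no
parameter inference from trajectories: phase durations come from the
literature-derived defaults above, and the supplementary equation listing
of the source study was not available, so the system is reconstructed from
its published description — constraints that *are* printed (transit
times, the elongation arithmetic, the division budget, the volume ratio,
plateau timing) are pinned by the test suite, while the G1 split
(`t_G1R`, `t_G1D`) and the IP/migration timescales are package defaults
that can be overridden in the YAML configuration.
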