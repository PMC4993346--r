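Package: nichegrowth
Title: Age- and Phase-Structured Modelling of the Embryonic Forebrain Stem-Cell Niche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic modelling of ventricular/subventricular-zone (VZ/SVZ)
    growth in the embryonic mouse forebrain. Radial glia are tracked by
    cell-cycle phase and mitotic age; cell fate (symmetric proliferation,
    asymmetric self-renewal, terminal differentiation) is controlled by a
    logistic rule on niche volume relative to a carrying capacity, and
    terminal differentiation occurs at a preset division cap. Includes a
    genotype-perturbation layer for cell-cycle mutants (S/G2 elongation with
    an extra available division, the developmental-delay hypothesis), a
    comparison engine for alternative growth hypotheses (rapid cycling,
    prolonged lag, linear fixed-pool growth), design-based stereology
    estimators (Cavalieri point counting, optical fractionator), and a
    seeded synthetic-specimen generator so the full measurement pipeline can
    be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
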