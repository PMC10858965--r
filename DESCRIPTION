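Package: nhejfret
Title: Single-Molecule FRET Analysis of NHEJ Synapsis and Ligase IV End Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two- and three-color single-molecule
    FRET trajectories of DNA double-strand-break repair by non-homologous end
    joining (NHEJ). Provides a stochastic kinetic simulator for Lig4-XRCC4
    recruitment, DNA-end engagement and short-range synapsis; a forward
    photophysics model (alternating-laser excitation, crosstalk, gamma,
    photobleaching, incomplete labeling); trajectory demultiplexing and
    intensity corrections with apparent FRET efficiencies; change-point and
    colocalization event detection; censored exponential-mixture dwell-time
    maximum likelihood with bootstrap confidence intervals; photobleaching-step
    stoichiometry estimation and synapsis-aligned summaries; and one-site
    binding-isotherm fitting for filter-binding dose series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
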