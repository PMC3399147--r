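Package: vegens
Title: Ensemble Uncertainty Analysis for High-Latitude Vegetation Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-form, LPJ-style plant-functional-type competition
    simulator for the northern high latitudes (45N poleward), driven by
    synthetic gridded climate-change scenarios, together with the machinery
    for Monte Carlo uncertainty analysis of its projections: stratified
    Latin hypercube sampling over a 13-parameter space, partial rank
    correlation coefficient (PRCC) sensitivity analysis with per-grid-cell
    importance maps, quantile-band ensemble summaries of foliage projective
    cover (FPC) and coverage area, and decomposition of projection spread
    into parameter-, climate-, and emission-induced components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
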