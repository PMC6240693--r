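Package: inpspectra
Title: Per-Cell Ice-Nucleating-Particle Spectra from Droplet Freezing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of well-plate droplet freezing assays for microbial ice
    nucleation studies. Computes frozen-fraction curves, performs background
    correction against buffer controls, estimates cumulative ice-nucleating
    particle (INP) concentrations per cell via the Vali equation with exact
    binomial confidence intervals and detection limits, merges dilution
    series, screens and classifies ice-nucleation-active (INA) strains by
    onset temperature, and infers the proteinaceous/soluble nature of the
    active compound from heat and filtration treatment contrasts using
    self-contained Kruskal-Wallis and Dunn post-hoc tests. Includes a
    Poisson droplet-freezing simulator with parametric per-cell spectra and
    strain-panel generation, plus strain metadata summaries (taxonomy rank
    assignment from alignment statistics, habitat strategy, survival and
    composition tables).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
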