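Package: flynav
Title: Modelling Olfactory Navigation in Walking Fruit Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling odor-guided navigation in walking Drosophila.
    Implements phenomenological ON (odor onset) and OFF (odor offset) response
    models built from adaptive Hill compression and linear or differential
    filtering, nonlinear least-squares fitting of those models and of Hill
    dose-response curves, a stochastic agent-based navigation model combining
    odor-driven modulation of ground speed and turn probability with
    wind-guided deterministic turning and optional bilateral antennal
    comparison, a behavioral trajectory pipeline (Butterworth filtering,
    orientation-flip correction, gait parameters, advection-delay warping,
    exclusion rules, paired signed-rank period statistics), synthetic stimulus
    and turbulent-plume generators, and evaluation statistics for
    source-finding performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
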