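Package: foplimpact
Title: Simulated Dietary and Mortality Impacts of 'High-in' Front-of-Pack Labelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A macrosimulation pipeline for estimating the potential dietary and
    mortality impacts of a mandatory 'high in' front-of-pack labelling (FOPL)
    policy. Generates synthetic repeated 24-hour dietary recall surveys with
    survey and replicate weights, estimates usual nutrient intakes with a
    one-part (amount-only) measurement-error model (Box-Cox transformed linear
    mixed model with back-transformation by Gauss-Hermite quadrature) and
    balanced repeated replication variance, applies food-class-specific
    counterfactual nutrient reductions observed under FOPL policies, and runs a
    comparative risk assessment that converts intake changes into diet-related
    non-communicable-disease deaths averted or delayed, with Monte Carlo
    uncertainty intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
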