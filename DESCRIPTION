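Package: reinpast
Title: Reindeer-Lichen Pasture Dynamics, Wastage Estimation and
    Bioeconomic Steady States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Seasonal simulation of ground-lichen pastures under reindeer
    grazing and trampling wastage in Finnish herding districts, with
    rotation exposure, arboreal-lichen and supplementary-feed substitution,
    infrastructure-induced wastage and heavy-metal-suppressed regrowth.
    Wastage-to-intake multipliers are estimated by maximising modeling
    efficiency (Nash-Sutcliffe type) under leave-one-out cross-validation,
    with a model-variant ablation battery, an age- and sex-structured herd
    model, and steady-state bioeconomic optimisation of herd size, harvest
    and supplementary feeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
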