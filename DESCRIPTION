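Package: activeLeveque
Title: Bacterial Surface Adhesion in Shear Flow via Active Leveque Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the rate at which motile bacteria adhere to surfaces in
    shear flow, combining two levels of description that cross-validate each
    other. An agent-based Langevin simulator evolves spheroidal swimmers
    (Jeffery rotation, rotational diffusion, self-propulsion) over an absorbing
    wall and records adhesion events and density fields. A closed-form boundary
    layer theory extends classic Leveque mass-transfer analysis to active
    swimmers: a shear- and shape-dependent effective diffusivity, a similarity
    solution for the depleted near-wall density, an adhesion-rate law with a
    critical shear rate of maximal adhesion, a scaling collapse of net
    adhesion, and a validity-regime classifier. Ships motility parameters for
    E. coli and P. aeruginosa and flow scenarios (catheters, intestine, river,
    artery).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
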