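Package: gcmigrate
Title: Inference of B Cell Migration Between Germinal Centers from Spatial BCR Repertoires
Version: 0.1.0
Authors@R:
    person("Repertoire", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolutionary analysis of B cell migration between germinal-center
    follicles from spatially resolved B cell receptor (BCR) heavy-chain
    repertoires. Provides lineage clustering, a somatic-hypermutation
    divergence clock, maximum-parsimony migration inference on lineage
    phylogenies, Poisson rate-homogeneity testing with resampling envelopes,
    post-migration fate analysis, and an agent-based synthetic tonsil
    simulator with full ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
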