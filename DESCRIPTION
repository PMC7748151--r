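Package: vitropt
Title: Surrogate Modelling and Evolutionary Optimization of Plant Tissue-Culture Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and optimizing plant tissue-culture media from
    Box-Behnken response-surface experiments. Fits surrogate models of explant
    growth responses by gene expression programming (Karva-encoded symbolic
    regression with protected arithmetic) and M5' model trees (standard-deviation
    reduction splitting with pruning), ranks medium components by the Gamma test
    (near-neighbour noise-variance estimation), and searches the fitted surrogates
    with mono-objective genetic algorithms, NSGA-II and multi-objective particle
    swarm optimization to propose media that jointly maximize proliferation,
    shoot length and quality while minimizing necrosis and hyperhydricity.
    Ships published pear-rootstock (OHF 69, Pyrodwarf) surrogate models as
    evaluable fixtures together with a synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
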