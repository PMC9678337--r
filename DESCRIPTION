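Package: hgtstab
Title: Stability of Microbial Communities with Mobile Resistance Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates eco-evolutionary dynamics of model microbiomes in which
    a costly stressor-resistance gene spreads between taxa by conjugation.
    Each community is a generalized Lotka-Volterra system with two
    compartments (gene-free and gene-bearing) per taxon. The package
    generates random community ensembles, runs a four-scenario perturbation
    protocol (with/without the resistance gene, with/without prior low-level
    stressor exposure), and computes per-taxon stability, community
    robustness, and the paired contrasts attributable to resistance (Delta-R)
    and to prior exposure (Delta-E), swept over gene mobility and community
    interaction structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
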