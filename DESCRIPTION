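Package: ecgem
Title: Construction and Analysis of Enzyme-Constrained Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds enzyme-constrained genome-scale metabolic models (ecGEMs)
    from COBRA-style model files by curating gene-protein-reaction rules with
    quantitative subunit stoichiometry, splitting reversible and
    isozyme-catalyzed reactions, parameterizing enzyme molecular weights and
    turnover numbers from local kinetics tables, and adding a single total
    enzyme pool constraint of the form sum(v*MW/(sigma*kcat)) <= Ptotal*f.
    Provides flux balance analysis (FBA), parsimonious FBA, flux variability
    analysis, phenotype phase plane scans, overflow-metabolism simulation with
    biomass-yield and enzyme-efficiency trade-off curves, kcat calibration
    against a target growth rate, and enzyme-cost-based discovery of
    metabolic-engineering targets. Ships a seeded synthetic toy-model
    generator with analytic oracles so the whole pipeline runs end-to-end
    without external databases. Linear programs are solved with GLPK.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    xml2,
    yaml,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
RoxygenNote: 7.3.3
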