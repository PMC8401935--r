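Package: fluxburden
Title: Constraint-Based Analysis of Recombinant Protein Burden in Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds recombinant-production variants of genome-scale metabolic
    models and analyses the metabolic burden of heterologous protein
    expression. Generates plasmid-replication and protein-synthesis reactions
    from sequence-level inputs, calibrates uptake and production fluxes from
    culture measurements, and runs flux balance analysis (FBA), flux
    variability analysis (FVA), production-envelope, differential-flux,
    carbon-source amendment and FSEOF overexpression-target analyses. Includes
    a minimal SBML Level 3 + FBC v2 reader/writer and a bounded-variable
    simplex solver, plus generators for synthetic networks and consumption
    time series with analytically known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
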