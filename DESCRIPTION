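Package: microfoodweb
Title: Soil Micro-Food-Web Analysis from Community Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the soil micro-food web from sample-by-genus
    count tables of bacteria, fungi, and nematodes. Computes alpha diversity
    (observed richness, Chao1, Shannon), the nematode faunal indices of the
    Ferris framework (enrichment, structure, basal and channel indices,
    maturity indices, trophic diversity, faunal-profile quadrants), nematode
    metabolic footprints and the functional-footprint rhombus, ternary
    energy-flow channel partitioning, and thresholded Spearman co-occurrence
    networks across kingdoms. Includes a negative-binomial synthetic community
    generator with planted correlation structure and a phosphorus-gradient
    scenario for end-to-end validation, plus a one-call pipeline that writes a
    reproducible results bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    withr,
    igraph
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
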