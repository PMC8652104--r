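Package: panpav
Title: Linearized Pangenome Presence/Absence Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model, analyse and render linear representations of pangenomes.
    Reads and writes BED-like presence/absence matrices of pangenomic blocks
    on a flattened pan-reference, classifies blocks into core and variable
    (dispensable) genome at a tunable presence threshold, detects hollow areas
    (maximal runs of consecutive blocks jointly absent from the same genomes),
    orders genomes by phylogeny or local presence patterns, linearizes GFA1
    variation graphs into presence/absence matrices, and renders the
    multi-track linear view (annotation beeswarm, core/variable, repetition
    and per-genome presence tracks) as deterministic SVG. Includes seeded
    synthetic-pangenome generators with planted, recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    BiocGenerics,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
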