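Package: nadkit
Title: Conservation Coloring, Variant Annotation, and Pathway Genetics for
    Chlamydomonas NAD+ Biosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for dissecting NAD+ biosynthesis genetics in the green
    alga Chlamydomonas reinhardtii. Implements the Colorfy
    column-conservation classifier for protein multiple sequence alignments
    (majority-identity / conserved-minority categories with percentage color
    bands), coding-sequence variant consequence calling (missense, nonsense,
    frameshift) with single-base reversion design and degenerate
    restriction-site scanning, a metabolite/reaction reachability engine for
    pathway completeness and supplement rescue predictions, meiotic progeny
    tallies with an exact missing-class test for synthetic lethality, a
    replicative-aging lineage simulator for flagellar-number pedigrees, and
    relative qRT-PCR quantification normalized to an internal control gene.
    Seeded synthetic-data generators provide ground-truth fixtures for every
    component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
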