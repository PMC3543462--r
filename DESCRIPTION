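Package: cystflux
Title: Acantharian V9 Metabarcoding Assignment and Sediment-Trap
    Strontium Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for cyst-forming Acantharia, marine
    protists that build celestite (SrSO4) skeletons and sink as
    reproductive cysts. Implements quality screening of V9 18S rRNA
    amplicon reads (exact primer matching with IUPAC-aware primers and a
    sliding 50-bp expected-error window filter), taxonomic assignment by
    optimal global pairwise alignment against a clade-annotated reference
    database with nearest-neighbour identity and last-common-ancestor
    tie-breaking, depth-zone community composition summaries, and a
    sediment-trap strontium flux analysis (background estimation,
    significance flagging, flux computation with propagated uncertainty,
    C:Sr carbon conversion and percent-of-POC contribution). Seeded
    simulators for clade-structured references, error-bearing reads and
    trap bottle series make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
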