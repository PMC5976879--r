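Package: bshscreen
Title: Discovery, Classification and Comparative Analysis of Bile Salt
    Hydrolases in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for mining bacterial genome sequences for
    bile salt hydrolase (BSH) enzymes and separating them from the closely
    homologous penicillin-V acylases (PVA). Screens six-frame translations
    of genome FASTA against curated reference proteins with local alignment,
    discriminates BSH from PVA candidates with profile hidden Markov models
    scored by the forward algorithm and decoy-calibrated E-values, collapses
    hits into representative clusters at an identity threshold, profiles
    alignment-column conservation to call motifs and audit active-site
    residues, builds neighbor-joining trees with bootstrap support, and
    summarises per-species repertoires and ecological lifestyle
    cross-tabulations. Includes a synthetic-data generator that plants
    homologous protein families in genome-like records so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    graphics,
    stats,
    utils,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
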