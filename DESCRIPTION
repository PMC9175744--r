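Package: signetpharm
Title: Signed Network Propagation and Drug Similarity for Systems Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers drug mechanism-of-action on disease networks by signed
    random walk with restart (SRWR) over activation/inhibition signaling
    networks, scores drug-target/disease-gene association as a permutation-null
    Z-score on random-walk influence vectors, compares drugs by chemical
    structure (circular fingerprints and Tanimoto similarity), interactome
    target-module separation (S_AB), and metapath functional similarity
    (PathSim) with hierarchical clustering, and validates propagated
    inhibition with hypergeometric enrichment. Includes a synthetic-data
    generator with planted drug-disease structure so the full pipeline is
    testable offline, and potency-unit arithmetic linking pIC50 and IC50.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    Matrix,
    igraph,
    jsonlite,
    withr,
    generics,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
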