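Package: signalcarver
Title: Condition-Specific Mechanistic Signaling Models from Multi-Omics
    Data and Signed Causal Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds mechanistic, condition-specific models of signal
    transduction downstream of a perturbed receptor.  Signed activities of
    transcription factors, kinases and phosphatases are inferred from
    differential transcriptomics and phosphoproteomics (footprint
    enrichment over signed regulons and a regulatory-phosphosite score),
    connected to the perturbation through all minimal-length causal paths
    of a signed prior-knowledge network, and pruned to the sign-consistent
    subnetwork that best explains the measurements.  Phenotype marker
    proteins are then read out from the optimized model as an in-silico
    validation.  A synthetic ground-truth generator emits matched
    transcriptome, proteome and phosphoproteome tables with a known signed
    network so every stage can be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
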