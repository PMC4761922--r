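Package: matriquant
Title: Spectral-Count Proteomics of Matrix-Enriched Tissue Extracts
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for label-free spectral-counting proteomics of
    extracellular-matrix-enriched tissue extracts. Provides total-spectra
    normalization, unpaired t-test differential expression with a
    unique-peptide inclusion filter, a spectra-per-kilodalton relative
    abundance index, principal component analysis and Pearson-correlation
    hierarchical clustering of samples and proteins, interaction-network
    construction with Markov clustering (MCL), per-subnetwork hypergeometric
    gene-ontology over-representation with a dominant-term call, and
    intersection of upregulated transcripts and proteins into a shared
    cross-omics signature. A negative-binomial synthetic-data generator with
    planted differential expression, planted network modules, and a
    controlled transcript overlap makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
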