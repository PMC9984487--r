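Package: ighconform
Title: Igh Locus 3D Conformation and V(D)J Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking the three-dimensional conformation of the mouse
    immunoglobulin heavy-chain (Igh) locus to V(D)J recombination outcomes.
    Provides a confined self-avoiding polymer ensemble as a null model for
    chromatin contacts, Knight-Ruiz balancing and quantile normalization of
    binned Hi-C contact matrices against that null, Hi-C difference maps,
    virtual 4C viewpoint profiles with dual-replicate peak calling,
    three-color DNA FISH configuration classification, 3C crosslinking
    frequency normalization, zone-of-influence (ZOI) repertoire statistics,
    and seeded synthetic-data generators emulating each input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
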