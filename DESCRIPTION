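Package: aqpscan
Title: Annotation, Classification and Expression Analysis of Plant Aquaporin Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide characterization of plant
    aquaporin (major intrinsic protein) gene families, modelled on the sweet
    cherry (Prunus avium) aquaporin roster. Extracts NPA motifs, the ar/R
    selectivity filter, Froger's positions and substrate
    specificity-determining positions (SDPs) from protein sequences by
    template alignment; classifies PIP/TIP/NIP/SIP/XIP subfamilies from motif
    signatures; infers transported substrates from per-substrate SDP consensus
    sets; scans promoters for stress-related cis-regulatory elements; derives
    exon-intron statistics from gene models; estimates Ka/Ks by the
    Nei-Gojobori (1986) method; and computes efficiency-corrected relative
    qPCR expression (Pfaffl 2001). Seeded synthetic-data generators with
    planted ground truth support end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
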