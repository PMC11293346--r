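Package: hitiseq
Title: Junction Read Analysis for AAV-Mediated Homology-Independent
    Targeted Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models CRISPR-Cas9 homology-independent targeted integration
    (HITI) experiments that deliver a promoter-less donor cassette from an
    AAV vector into a nuclease-cut genomic locus.  Builds the expected
    junction reference sequences for every integration outcome class
    (clean HITI in both orientations, ITR-retained vector integration,
    vector fragment capture, indels, large deletions and inversions),
    simulates junction-spanning long reads and short amplicon reads from a
    stated outcome mixture with platform error models and a truth sidecar,
    demultiplexes barcoded long reads under an edit-distance budget,
    classifies reads at the 5' and 3' junctions by windowed insertion
    counting and ITR sequence content, quantifies amplicon indels in a
    fixed window around the cut site, assigns vector origins to captured
    insertions, and aggregates everything into an outcome report including
    the productive-integration arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
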