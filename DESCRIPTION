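Package: ptsHGT
Title: Cataloguing Bacterial PTS Enzyme II Gene Sets and Screening Them for Horizontal Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Catalogues phosphotransferase-system (PTS) enzyme II genes from
    annotated bacterial genomes, classifies them into substrate families by
    domain architecture, assembles them into operon-like gene sets, partitions
    set GC content into groups by exact one-dimensional clustering, scans
    gene neighbourhoods for regulatory and mobility markers (sigma-54, sugar
    isomerase, insertion sequences), builds neighbour-joining trees with
    bootstrap support from scratch, and integrates GC anomaly, gene-tree /
    species-tree incongruence and IS flanking into a per-set horizontal gene
    transfer verdict. A deterministic synthetic-genome generator with a
    ground-truth manifest makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
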