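Package: aapcensus
Title: Multi-Evidence Census of Actin-Associated Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a census of actin-associated proteins (AAPs) by integrating
    three lines of evidence: partners of a curated actin query set in scored
    protein-protein interaction databases filtered at per-database thresholds,
    membership of classical actin-binding Pfam domain families in filtered and
    overlap-resolved domain architectures, and Gene Ontology annotation mining
    (protein-level annotations, Pfam2GO domain mappings, and curated lists).
    Includes HMM-scan hit filtering and greedy overlap resolution for domain
    architecture assignment, membrane/lipidation/tissue-expression/COG
    classification of census entries, hypergeometric term enrichment with
    Benjamini-Hochberg false discovery rate control against a whole-proteome
    background, and a seeded synthetic-data generator that emulates every
    consumed input format with planted ground truth so the full pipeline is
    testable without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
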