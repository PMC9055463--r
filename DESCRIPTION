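Package: genusprimer
Title: Genus-Specific 16S rRNA qPCR Primer Design and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design and validation toolkit for genus-specific 16S rRNA gene
    qPCR primers in microbiome studies. Enumerates degenerate candidate
    primers from labelled multiple sequence alignments under explicit
    thermodynamic (nearest-neighbor melting temperature, hairpin and dimer
    free energy) and compositional (GC content, GC clamp) filters, screens
    coverage and specificity by mismatch-tolerant in silico PCR with a
    3'-exact zone, fits qPCR standard curves with amplification-efficiency
    quality control and copy-number estimation, and measures Spearman
    rank-correlation concordance between qPCR copy numbers and metagenomic
    relative abundance. Ships a transcribed 11-genus fish-microbiome primer
    panel and a seeded synthetic 16S-like family generator for end-to-end
    testing without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
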