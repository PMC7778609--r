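Package: fcsortseq
Title: Sort-Seq Analytics for Mammalian-Display Fc Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for structure-guided Fc variant library screening by
    mammalian cell display and FACS selection. Identifies candidate mutagenesis
    positions at the Fc/Fc-gamma-receptor interface from PDB structures, designs
    two-position degenerate (NNK) libraries with theoretical-diversity and
    transformant-coverage statistics, simulates multi-round FACS selection campaigns
    and emits barcoded FASTQ reads with ground truth, processes multi-sample amplicon
    FASTQ into DNA- and amino-acid-level variant count tables (quality filter,
    barcode demultiplexing, constant-region trimming, frame +1 translation),
    computes enrichment scores, cumulative-frequency curves, copy-threshold
    beneficial-variant calls and per-position amino-acid probability matrices with
    sequence-logo color classes, and reproduces receptor-selectivity KD ratio tables
    and LDH-release percent-cytotoxicity values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
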