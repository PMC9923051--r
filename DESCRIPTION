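Package: egusimap
Title: Segregation Analysis, BSA-Seq QTL Scanning, and Fine-Mapping of the
    Watermelon Egusi Seed Trait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genetic dissection toolkit for the egusi (thin seed coat) trait
    in watermelon and similar two-locus epistatic traits. Provides a forward
    simulator of biparental crosses (F1, F2, BC1F1, BC1F2) under a
    configurable two-locus penetrance model with Haldane recombination;
    chi-square goodness-of-fit tests of phenotype segregation against
    Mendelian and epistatic ratios with exact ratio enumeration and model
    ranking; bulked-segregant-analysis sequencing (BSA-seq) QTL detection
    using per-pool SNP indices, delta(SNP-index) sliding windows, and
    per-window permutation thresholds; recombinant-driven fine-mapping of a
    locus to a minimal marker-flanked interval from graphical genotypes; and
    CAPS/dCAPS marker feasibility screening from SNP flanking sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
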