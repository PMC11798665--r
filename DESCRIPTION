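Package: cfmerge
Title: Cell-Free DNA Fragmentomics with Multi-Epigenetically Regulated Gene
    Selection for Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts fragmentomic and cell-free epigenomic features from
    plasma cfDNA sequencing-derived inputs at gene resolution: end and
    breakpoint motif profiles, fragment size ratios and distributions,
    motif entropy and nuclease F-profile deconvolution, promoter H3K4me3
    RPKM, promoter CpG methylation and TSS nucleosome-depleted-region
    scores. Integrates rank-based differential evidence across the three
    epigenomic layers to select multi-epigenetically regulated genes
    (MERGEs), then trains a stacked extremely-randomized-trees ensemble on
    MERGE-restricted fragmentomic features and evaluates it with Wilson
    confidence intervals, bootstrap AUC intervals and the DeLong test. A
    synthetic-cohort generator with planted, gene-anchored effects provides
    recoverable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    glmnet,
    ranger,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
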