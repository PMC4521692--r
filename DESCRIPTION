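Package: dmcscreen
Title: Genome-Wide Screening of Differentially Methylated CpG Sites for
    Fetal Epigenetic Biomarkers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A five-stage screening pipeline for differentially methylated
    CpG sites (DMCs) between maternal blood cell DNA and chorionic villus
    (placental) DNA on 450K-style methylation arrays: complete-case
    filtering of beta-value matrices, per-CpG Wilcoxon rank-sum testing
    with Benjamini-Hochberg false discovery rate control, strict
    hypo/hyper-methylation thresholding, overlap of the interrogated CpG
    with methylation-sensitive restriction enzyme (MSRE) recognition
    sites, and per-sample consistency filtering.  Includes mapping of
    candidate markers to chromosomes and micro-deletion syndrome regions,
    replicate quality control via SNP control probes, and a synthetic
    data generator that emulates the statistical structure of a two-group
    beta-value study so the whole pipeline is testable without array
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
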