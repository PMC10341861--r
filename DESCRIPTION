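Package: dmrlinc
Title: Integrative Discovery of DMR-Regulated lncRNAs and Their Cis Targets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative epigenomics pipeline that links whole-genome
    bisulfite sequencing methylation with transcript-level RNA-seq expression
    to nominate long non-coding RNAs (lncRNAs) under the control of nearby
    differentially methylated regions (DMRs), and the proximal protein-coding
    transcripts those lncRNAs may regulate in cis. Stages cover CpG coverage
    filtering, a permutation-based DMR caller, negative-binomial Wald
    differential expression with median-of-ratios size factors, windowed
    methylation-expression correlation integration, reference-based cell-type
    deconvolution by robust regression, and cross-dataset verification of
    lncRNA-protein correlations. A synthetic-data module generates complete
    joint methylation/expression cohorts with planted DMR-lncRNA-protein
    regulatory triplets so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    MASS,
    jsonlite,
    yaml,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
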