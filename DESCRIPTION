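Package: twinqtl
Title: Twin-Based Methylome and Transcriptome QTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Twin-cohort genetic analysis of tissue methylomes and
    transcriptomes: ACE variance decomposition of CpG methylation, cis/trans
    meQTL and eQTL mapping with twin-aware permutation FDR and
    beta-approximation gene-level FDR, exact stepwise conditional signal
    selection, Bayesian colocalization of meQTL and eQTL signals with
    count-derived priors, SNP-methylation-expression mediation (SME/SEM)
    with Sobel tests, cross-dataset replication statistics (Storey pi1,
    error-aware effect correlation r_b), and interval/catalog enrichment.
    Includes a synthetic twin-cohort generator with planted genetic
    architecture so every stage is testable without access to individual-level
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
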