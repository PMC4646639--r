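Package: mlpaseq
Title: Copy-Number Calling for Sequencing-Based Multiplex
    Ligation-Dependent Probe Amplification Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for gene copy-number detection from sequencing-based
    MLPA (multiplex ligation-dependent probe amplification) assays, in
    which ligated probe pairs are amplified and counted by sequencing
    rather than sized by capillary electrophoresis. Provides probe-design
    validation and 20-base ligation-junction key derivation, exact k-mer
    read counting from FASTQ with adapter trimming and library QC,
    within-library depth normalization against non-amplification probes,
    control-baseline copy-number ratios, exon-level aggregation,
    ratio-band CNV classification with germline/somatic origin
    assignment from blood-tumour pairs, an analytic tumour-purity
    dilution model, a truth-aware cohort simulator, and a manifest-driven
    end-to-end pipeline with per-sample summary reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
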