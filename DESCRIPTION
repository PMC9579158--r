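Package: dysregr
Title: Multi-Dataset Transcriptomic Dysregulation Scoring for Reprogrammed Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates differential-expression evidence for Parkinson's disease
    versus control reprogrammed-neuron transcriptomes across multiple bulk and
    single-cell RNA-seq datasets. Provides sample- and cell-level quality-control
    filters (detected genes, housekeeping-gene detection, mapping rate, doublet
    cut-offs), dual differential-expression testing on counts and TPM with
    logit-method p-value combination, desirability-based per-gene dysregulation
    scores within and across datasets with fold-change-concordance weighting,
    self-contained pre-ranked gene-set enrichment analysis with gene-permutation
    FWER/FDR control, pseudobulk aggregation, and a synthetic multi-dataset
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
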