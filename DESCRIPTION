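Package: mixsign
Title: Single-Subject Pathway Analysis with Functionally Signed Gene Set
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies biologically altered transcripts from a single
    paired transcriptome sample (case versus control from the same subject
    or genotype) by fitting a two-component Gaussian mixture to absolute
    log2 fold changes, tests Gene Ontology Biological Process terms for
    overrepresentation of the altered transcripts with one-sided Fisher's
    exact tests and Benjamini-Yekutieli correction, and assigns each
    significant term a categorical functional direction (activated,
    reduced activity, bidirectionally altered, or ambiguous) by flipping
    the functional sign of genes annotated to direct negatively_regulates
    child terms. Includes OBO/GAF readers with true-path annotation
    propagation, a synthetic-data generator with implanted, direction-known
    pathway perturbations, and replicate-reproducibility metrics (ROC/AUC,
    precision-recall, Spearman rank correlation of odds ratios, overlap
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    pROC,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
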