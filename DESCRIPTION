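Package: mtwas
Title: Multi-Tissue Expression and Splicing TWAS with Cauchy Aggregation,
    Conditional Analysis, and Gene-Level Fine-Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-wide association studies (TWAS) of
    case-control traits from GWAS summary statistics, SNP-weight prediction
    models and a linkage-disequilibrium (LD) reference. Implements
    summary-statistic harmonization and inverse-variance fixed-effects
    meta-analysis, Gaussian conditional-mean z-score imputation at model
    SNPs missing from the GWAS, the summary-based per-tissue TWAS z-score,
    two-step aggregated Cauchy association test (ACAT) combination of
    intron-level and tissue-level p-values, conditional analysis of TWAS
    signals on GWAS index variants and the reverse mediation analysis with
    proportion-mediated estimates, and probabilistic gene-level fine-mapping
    with marginal posterior inclusion probabilities and credible sets.
    Includes a synthetic-data generator (LD-structured genotypes, sparse
    multi-tissue eQTL/sQTL weight models, case-control summary statistics
    with ground truth) so the full pipeline can be exercised and calibrated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
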