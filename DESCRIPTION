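Package: panprog
Title: Multi-Omics Prognostic Biomarker Discovery by Cox Voting and Score Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies prognostic biomarker genes by integrating four omics
    layers (gene expression, somatic copy-number alteration, DNA methylation,
    and miRNA expression mapped to target genes) measured on a common set of
    tumor samples with right-censored survival. Each gene is screened per
    layer with a univariate Cox proportional-hazards model and voted
    survival-related at p < 0.05; genes voted in at least two layers enter a
    per-gene multivariate Cox fit across the four layers, gated on the
    likelihood-ratio, Wald, and score tests. Genes are ranked by
    Score = A + B + C + D + GS, the vote count plus the mean per-sample risk
    score. Includes harmonization of TCGA-style matrices (missingness and
    expression filters, duplicate-probe averaging, miRNA-target mapping,
    z-score normalization), a validation battery (resampled Harrell C-index,
    Kaplan-Meier / log-rank stratification, decision-curve analysis),
    hypergeometric gene-set enrichment, SAM-style differential expression,
    and a synthetic multi-omics survival-data generator with planted driver
    genes for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
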