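# panprog

Multi-omics prognostic biomarker discovery by Cox voting and Score
ranking.

## What it does, and for whom

Given four omics layers measured on the same tumor samples — gene
expression (GE), somatic copy-number alteration (SCNA), DNA methylation
(DM) and miRNA expression mapped to target genes (ME) — plus survival
follow-up, `panprog` ranks genes as candidate prognostic biomarkers and
validates the resulting panel. It is aimed at computational biologists
working with TCGA-style cohorts who want a transparent, fully reproducible
alternative to black-box multi-omics survival models.

The procedure:

1. **Screen + vote.** For every gene and layer, a univariate Cox
   proportional-hazards fit `h(t|x) = h0(t) exp(βx)`; the gene is voted
   survival-related on that layer when the likelihood-ratio p < 0.05. The
   four flags are A (GE), B (SCNA), C (DM), D (ME). Genes voted on ≥ 2
   layers become candidates.
2. **Integrate.** Per candidate, one multivariate Cox fit over its four
   layer vectors, kept only if the likelihood-ratio, Wald and score tests
   all have p < 0.05. With coefficients `B` and per-sample omics vector
   `V`: per-sample risk `RS = B·V`, gene score `GS = mean(RS)`, and

   ```
   Score = A + B + C + D + GS
   ```

3. **Rank.** Genes sorted by Score; the top 10 form the biomarker panel.
4. **Validate.** Resampled Harrell C-index of the panel risk model (100
   draws of 90% of samples), median-split Kaplan–Meier / log-rank
   stratification, decision-curve analysis
   (`net benefit = TP/n − FP/n · p_t/(1−p_t)`), hypergeometric gene-set
   enrichment and SAM-style differential expression.

A synthetic multi-omics generator with planted driver genes
(`generate_dataset()`) provides ground truth for every stage, with the
biologically expected cross-layer correlation signs (DM and ME
anti-correlated with GE, SCNA positively correlated).

See `vignettes/panprog-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

Simulate a cohort of 300 samples × 200 genes with three planted two-layer
drivers, run the full scoring pipeline, and validate the panel:

```r
library(panprog)

cfg <- sim_config(n_genes = 200, n_samples = 300, n_drivers = 3,
                  driver_layers = list(c("GE", "SCNA"), c("GE", "DM"),
                                       c("DM", "ME")),
                  effect_size = 1.0, censor_rate = 0.3, seed = 1)
sim <- generate_dataset(cfg)
sim$truth
#>    gene_id GE SCNA DM ME
#> 1 gene0057  1    1  0  0
#> 2 gene0025  1    0 -1  0
#> 3 gene0161  0    0 -1 -1

votes <- univariate_screen(sim$dataset)
res   <- score_genes(sim$dataset, votes)
panel <- rank_genes(res$records, k = 5)
panel[, c("gene_id", "A", "B", "C", "D", "gs", "score", "rank")]
#>    gene_id A B C D         gs    score rank
#> 1 gene0057 1 1 1 1  1.2170698 5.217070    1
#> 2 gene0025 1 1 1 1  1.2068690 5.206869    2
#> 3 gene0042 1 1 1 1 -0.1535578 3.846442    3
#> 4 gene0168 0 1 0 1  1.3612752 3.361275    4
#> 5 gene0161 1 1 1 1 -1.6514893 2.348511    5

cindex_resampling(panel, sim$dataset, frac = 0.9, reps = 100, seed = 2)
#> <cindex_distribution> 100 reps at 90%: median C = 0.890 (sign-test p = 7.89e-31)

risk   <- panel_risk_scores(panel, sim$dataset)
groups <- stratify(risk)
logrank_test(groups, sim$dataset$clinical$time, sim$dataset$clinical$event)
#> [1] 1.29e-56
```

All three planted drivers (`gene0057`, `gene0025`, `gene0161`) appear in
the top 5: the vote count puts them in the 4-vote tier and GS orders genes
within tiers. The median resampled C-index of 0.89 (1 = perfect ranking of
failure times, 0.5 = random) and the log-rank separation of the
median-split risk groups confirm the panel carries real prognostic signal.

`run_pipeline()` executes the same chain from TSV inputs (including
harmonization: sample-type and missingness filters, duplicate-probe
averaging, miRNA→gene mapping, z-score normalization) and writes every
intermediate table plus a run manifest.

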