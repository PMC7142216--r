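---
title: "Multi-omics prognostic gene ranking: models and methods"
author: "panprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics prognostic gene ranking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panprog)
```

# The problem

Tumor cohorts profiled on several molecular layers — gene expression (GE),
somatic copy-number alteration (SCNA), DNA methylation (DM) and miRNA
expression (ME) — carry partly redundant, partly complementary information
about patient survival. A gene may look unremarkable in expression yet show
a strong survival association through its copy number or promoter
methylation. `panprog` implements a voting-and-scoring procedure that
integrates the four layers per gene, ranks genes as candidate prognostic
biomarkers, and validates the resulting panel.

# The model

## Per-layer screening and voting

For each gene $g$ and each layer $k$, a univariate Cox proportional-hazards
model

$$ h(t \mid x) = h_0(t)\, e^{\beta x_{gk}} $$

is fitted with that layer's (normalized) value as the single covariate. The
gene is *voted* survival-related on the layer when the likelihood-ratio
test of the fit has $p < \alpha$ (default $\alpha = 0.05$). The four vote
flags are written $A, B, C, D$ for GE, SCNA, DM and ME respectively; a gene
is a **candidate** when at least `min_votes = 2` of its four flags are 1.
The sign of $\beta$ is kept for interpretation: $\beta > 0$ marks a risk
factor on that layer.

No multiplicity correction is applied inside the screen — the vote
threshold is a raw per-test level, and the two-of-four requirement is the
mechanism that suppresses isolated false positives. A Benjamini–Hochberg
variant can be obtained by adjusting the reported per-layer p-values, but
it is deliberately not the default because the Score procedure is defined
on raw votes.

## Per-gene integration and the Score

Each candidate enters one multivariate Cox fit over its four layer vectors:

$$ h(t \mid M_g) = h_0(t) \exp(\beta_1 \mathrm{GE} + \beta_2 \mathrm{SCNA}
   + \beta_3 \mathrm{DM} + \beta_4 \mathrm{ME}), $$

gated on **all three** overall tests — likelihood ratio, Wald and score
(log-rank) — at $p < 0.05$. Genes failing any test are excluded from the
ranking (they remain visible in a rejects table). For a retained gene with
coefficient vector $B$ and per-sample layer vector $V_j$,

$$ \mathrm{RS}_j = B \cdot V_j, \qquad
   \mathrm{GS} = \frac{1}{m} \sum_{j=1}^m \mathrm{RS}_j, \qquad
   \mathrm{Score} = A + B + C + D + \mathrm{GS}, $$

with $m$ the number of samples entering the fit. The integer part of the
Score counts the layers on which the gene is survival-related; GS is a
continuous refinement reflecting the cohort-average predicted log relative
hazard of the gene's panel of four covariates. Genes are ranked by Score
descending; exact ties (possible only when GS coincides) break by vote sum,
then the multivariate likelihood-ratio p-value, then gene id, so the
ranking is fully deterministic. The top `k = 10` genes form the biomarker
panel.

Two robustness variants are provided. `score_variant_voted_layers_only()`
refits each gene using only its voted layers and recomputes the Score with
the reduced coefficient vector; on synthetic data its ranking correlates
with the full ranking at Spearman $\rho > 0.8$. `merged_matrix_screen()`
treats each gene–layer pair as a separate feature of one merged matrix and
counts, per gene, the features whose multivariate Wald test is significant.
On our synthetic fixtures both routes recover the planted drivers; the full
containment of the merged-route genes within the voting candidates is an
empirical observation, not a structural guarantee, because conditioning on
the other layers can flip individual borderline genes in either direction.

# Harmonization

Raw TCGA-style matrices pass through, in order: clinical sample-type
filtering (code `"01"`, primary solid tumor), removal of genes missing in
more than 5% of samples (strict inequality, residual gaps imputed by the
gene-row mean), abundance filters (GE kept when positive in more than 50%
of samples; ME kept when above 1 in more than 10%), duplicate-probe
averaging, miRNA→gene mapping, sample/gene intersection across the four
layers and the clinical table, and z-score normalization. All threshold
comparisons are strict (`>`), exactly as stated by the filtering rules.

miRNA expression is attributed to target genes through a curated
interaction table filtered to interactions with at least 5 supporting
experiments and anti-correlation in at least one cancer type; a gene bound
by several surviving miRNAs receives their per-sample mean.

**Z-score scope.** Normalization standardizes the *whole matrix* (global
mean and standard deviation), not each gene row. Per-gene centering would
set every gene's mean to zero and with it drive every gene's GS toward
zero, collapsing the Score to the bare vote count; global standardization
preserves between-gene location differences and keeps GS informative. A
`per_gene` option exists for sensitivity analysis. Normalized values are
rounded at the fourth decimal place using round-half-to-even, a
deterministic, platform-stable convention.

**Order of operations.** Filters run before alignment; z-scoring runs after
alignment, so the normalization constants reflect exactly the analyzed
cohort.

# Survival primitives

Cox models are fitted by Newton iteration with step-halving via the
`survival` package's fitting engine (Efron tie approximation by default,
Breslow available; tolerance $10^{-9}$, at most 50 iterations). Three
conditions are treated as *non-convergence*, reported as a flag rather than
an exception so genome-wide screens never abort: reaching the iteration
cap, a non-positive-definite information matrix, and runaway coefficients
($|\beta| > 15$ per z-unit, the signature of monotone partial likelihood).
Non-converged genes vote 0 and are rejected from integration.

Harrell's concordance index is computed by exhaustive pair enumeration: a
pair is comparable iff the smaller observed time belongs to an event (tied
times are incomparable), concordant when the shorter-lived subject has the
higher risk, with risk ties counting 1/2. Kaplan–Meier curves and the
two-sample log-rank test delegate to `survival::survfit()` and
`survival::survdiff()`.

# Validation battery

`cindex_resampling()` repeats 100 times: draw 90% of the samples without
replacement, fit the panel risk model (one Cox fit over all $4k$ panel
covariates) on the subsample, and evaluate Harrell's C of the fitted risk
on the same subsample. The C-index is evaluated on the fitting subsample —
an optimistic convention appropriate for describing discrimination of the
fitted model; the distribution over subsamples, not a held-out error, is
the reported object. A one-sided sign test against median 0.5 accompanies
the distribution (the choice of test is this package's: "significantly
above 0.5" needs an explicit test, and the sign test makes no distributional
assumption on the C values).

Panels of 40 collinear covariates frequently produce singular information
matrices on subsamples; when the plain fit fails, the panel fit is
ridge-stabilized starting at penalty $10^{-6}$ and escalating tenfold until
the fit succeeds.

Risk groups are split at the median risk score (ties to the low group),
giving balanced groups for Kaplan–Meier display and the log-rank test.

`decision_curve()` computes, per threshold probability $p_t$,

$$ \mathrm{net\ benefit}(p_t) = \frac{TP}{n} - \frac{FP}{n}
   \frac{p_t}{1 - p_t}, $$

alongside the treat-all line
$\pi - (1-\pi) p_t/(1-p_t)$ (prevalence $\pi$) and the treat-none line at
zero. The default grid is $p_t \in \{0.01, \dots, 0.80\}$ in steps of
0.01, the conventional range. Because a Cox linear predictor is not a
probability, `risk_to_probability()` maps risk to event probability by
logistic regression of the observed event indicator on the risk score —
the simplest monotone calibration; any monotone alternative leaves the
curve's ordering arguments unchanged.

# Enrichment and differential expression

Gene-set enrichment uses the upper-tail cumulative hypergeometric
probability $P(X \ge i)$ for an overlap of $i$ query genes with an
$M$-gene term inside an $N$-gene universe and an $n$-gene query,
$$ P = \sum_{j \ge i} \binom{M}{j}\binom{N-M}{n-j} \Big/ \binom{N}{n}, $$
the standard normalized form of the cumulative test. Raw $p < 0.05$ flags
significance (matching the screening convention); BH-adjusted values are
reported alongside. GMT collections can be restricted to a namespace (for
GO, biological-process terms).

SAM-style differential expression uses the moderated statistic
$d_g = (\bar{x}^A_g - \bar{x}^B_g)/(s_g + s_0)$. The fudge constant $s_0$
is fixed at the 5th percentile of the gene-wise pooled standard errors — a
deterministic simplification of the original coefficient-of-variation
minimization that damps small-variance genes the same way. q-values come
from group-label permutations: at each observed $|d|$ cutoff the estimated
false calls are the median permuted exceedance count, divided by the
observed count and monotonized. A gene is called at $q < 0.05$ and
$|\log_2 \mathrm{FC}| > 1$, with fold change computed from group means of
the un-logged values with a pseudo-count of 1.

# The synthetic-data generator

`generate_dataset()` supplies ground truth for every downstream stage. Per
gene, a latent standard-normal activity factor is mixed into each layer
with signed loadings — positive for GE and SCNA, negative for DM and ME —
plus independent noise, which guarantees the biologically expected
correlation signs (methylation and miRNA anti-correlated with expression,
copy number positively correlated) at magnitude `cross_layer_rho` without
specifying a full covariance. GE and ME are shifted to abundance-like
positive scales so the harmonization filters behave as on real data; SCNA
and DM stay centered. Survival times are exponential with rate
$h_0 e^{\mathrm{lp}}$ (constant baseline — the simplest model satisfying
proportional hazards); censoring is an independent exponential whose rate
is solved numerically so the expected censored fraction matches
`censor_rate` (random censoring, keeping the C-index interpretation
clean). Missing entries are injected uniformly at random and duplicate
probe rows appended when requested, to exercise the filters.

**Signed planted effects.** A driver's hazard effect is carried by its
activity, so the planted per-layer log hazard ratio is `effect_size`
multiplied by the layer's loading sign. Planting the same positive effect
on, say, GE and DM — two anti-correlated readouts of the same activity —
would make the two contributions cancel in the linear predictor, a
configuration the generator's own correlation structure marks as
incoherent.

**Defaults as study conditions.** `cross_layer_rho = 0.5` (mid-range
coupling: strong enough that the layers genuinely share signal, weak
enough that each layer retains independent information),
`baseline_hazard = 10^{-3}`/day (median survival of roughly two years for
a baseline subject), `censor_rate = 0.3` (typical of solid-tumor
follow-up), `effect_size = 1` per SD for planted drivers. These were fixed
once as the simulation conditions for the whole test battery.

**Non-collapsibility of marginal Cox coefficients.** With several drivers,
the univariate (marginal) Cox coefficient of any single layer is
attenuated relative to the planted conditional effect, because the other
drivers act as unobserved heterogeneity — with five independent
unit-effect drivers the marginal coefficient settles near 0.6, not 1.0,
even at large $n$. This is a property of proportional-hazards models, not
a bug: parameter-recovery tests therefore check the *joint* multivariate
fit against the planted effects, and single-driver configurations for
univariate recovery.

**What the generator does not emulate:** tumor purity, batch effects,
subtype mixtures, non-proportional hazards, informative censoring, heavy
tails or zero inflation of expression. Tests passing on this generator
demonstrate the machinery is correct under the declared model; they do not
certify performance on real cohorts.

# Problem sizes used by the test battery

The shipped validation battery runs at desk scale, chosen to estimate each
property stably: driver recovery at 500 genes × 300 samples × 20 seeds
(five two-layer drivers, mixed layer pairs), screen calibration at 1000
null genes, the multi- vs single-omics contrast at 200 genes × 300 samples
× 10 seeds with 100 resampling repetitions, Cox oracle equivalence on 20+
datasets of up to 8 subjects against a $10^{-4}$-resolution grid search,
and hypergeometric enumeration over every instance with a universe of at
most 12 genes.

# Known limitations

* The screen refits one Cox model per gene × layer; at genome scale
  (2×10^4 genes) a single cancer run is minutes, not seconds.
* GS depends on the normalization scope; with per-gene z-scoring it is
  identically ~0 and the Score degenerates to the vote count (this is why
  global scope is the default).
* The resampled C-index is an in-sample quantity; the optional train/test
  split (fit on 90%, score the held-out 10%) gives honest but noisier
  estimates and is clearly labeled as a non-default variant.
* Votes are raw per-test decisions; at `alpha = 0.05` and four layers the
  expected false-candidate rate among null genes is small but non-zero,
  and correlated layers make multi-layer false votes more likely than
  independence would suggest.
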