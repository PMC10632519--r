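---
title: "Methods: prognostic module analysis of tumor-adjacent normal tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic module analysis of tumor-adjacent normal tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tanprog)
```

This vignette documents the models, parameter choices, numerical decisions
and known limitations behind `tanprog`. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The scientific setting

Matched cohorts of early-stage lung adenocarcinoma contribute, per patient,
one tumor sample and one tumor-adjacent normal (TAN) sample of
histologically normal lung, plus long-term follow-up. The working
hypothesis is that the TAN transcriptome — in particular the activity of an
inflammatory co-expression program — predicts later disease progression
better than tumor mutations or tumor expression do. The package implements
the full analysis chain needed to evaluate that hypothesis and a synthetic
cohort generator that plants exactly the structure the chain is supposed to
detect, so each claim about the pipeline is testable end to end.

## Preprocessing

Counts are normalized with median-of-ratios size factors: for sample $s$,
$f_s = \mathrm{median}_g\, c_{gs} / \tilde{c}_g$ over genes whose geometric
mean $\tilde{c}_g$ across samples is strictly positive. The transform is
$\log_2(c_{gs}/f_s + 1)$, recorded in the matrix's `transform_tag`. This is
a monotone, variance-damping substitute for a model-based variance
stabilizing transformation; because every downstream consumer re-scales
genes to z-scores, the difference between the two monotone transforms is
largely absorbed. Gene-wise z-scores use the sample standard deviation
($n-1$); zero-variance genes are zeroed and flagged rather than dropped so
matrix shapes stay stable across cross-validation folds.

Outcome labels use a 5-year boundary of 1826 days, inclusive on the event
day. Recurrence means locoregional or systemic events only; progression
additionally counts second primaries and, for positives, has no time limit,
while negatives require at least five years of event-free follow-up —
patients with neither are excluded. Somatic variants are kept when
VAF > 1%, total reads ≥ 100, alternate reads ≥ 5, VAF > 5× the matched
normal, the variant is in COSMIC, and its gnomAD population frequency is
below 0.1%; tumor mutational burden is the raw count of retained variants
per sample (no per-megabase normalization — the panel size is a constant of
the assay, and only relative comparisons are made).

## Module discovery and scoring

PCA treats genes as observations and samples as features (columns centered,
not rescaled); clustering runs on the leading principal components
(default 10, the analysis convention). Modules come from classical PAM:
greedy BUILD seeding followed by SWAP local search that accepts any
medoid/non-medoid exchange strictly lowering the summed Euclidean distance
to assigned medoids, to a local optimum. All ties break toward the lowest
gene index, making the clustering deterministic; a `seed` argument exists
only for interface symmetry. The module score of a sample is the mean
z-score of the module's genes, with z-scores computed jointly over tumor
and TAN samples — the tissue contrast in the score tables is only
meaningful on a shared scale, and re-scaling per tissue would erase it.

Tissue and progression contrasts use the two-sided Wilcoxon rank-sum test:
exact enumeration when both groups have at most 10 tie-free observations,
otherwise the normal approximation with continuity and tie corrections.
Per-module results carry BH-adjusted p-values, and multi-module claims
("no tumor module is significant") are made on the adjusted values — a
20-module scan at a raw 0.01 threshold would produce a false positive in
roughly 18% of null cohorts, which is a property of multiplicity, not of
the data. Where differential-expression flags are needed and no external
model-based results are supplied, a rank-based substitute (per-gene
Wilcoxon + BH at 0.05, direction by median shift) is provided; its flags
feed the per-module percent-up/percent-down summaries.

Reduced signatures rank a module's genes by mean expression on the
*pre-z-scoring* transformed matrix (average expression is a property of the
measured scale, not of the standardized one) and report the Pearson
correlation between the reduced and full score vectors.

## Enrichment

Module-vs-gene-set enrichment is the one-tailed Fisher test,
$p = P(X \ge \text{overlap})$ under the hypergeometric null, with the odds
ratio taken from the 2×2 table (0.5 added to zero cells for the ratio
only, never for $p$). The universe is the gene list submitted to module
discovery — enrichment conditions on the clustering input space, since
genes outside it had no chance to be assigned. BH adjustment runs jointly
across the full module × set grid.

## The recurrence classifier

The model is logistic regression with the elastic-net penalty, fitted by
cyclic coordinate descent on the IRLS quadratic approximation with
soft-thresholding; the intercept is unpenalized and features are expected
standardized. The printed form of the loss adds the log-likelihood to the
penalty; the only convex reading — and the convention of the standard
software for this model — minimizes the penalized *negative*
log-likelihood, which is what `enet_fit()` does. Convergence is declared
when a fresh re-linearization no longer moves any coefficient beyond the
tolerance (default 1e-7); non-convergence within the sweep budget is an
error, not a silent result.

The λ path starts at
$\lambda_{max} = \max_j |\sum_i x_{ij}(y_i - \bar{y})| / (N\alpha)$
(the smallest penalty with an all-zero solution; α = 0 uses the standard
0.001 surrogate) and descends log-linearly over 100 values to
$10^{-2}\lambda_{max}$. The mixing grid is $\alpha_n = (n/20)^2$,
$n = 0..20$ — 21 values concentrated toward ridge. Inner cross-validation
scores each (α, λ) by mean out-of-fold binomial deviance with predictions
clipped to $[10^{-12}, 1-10^{-12}]$; ties prefer the larger λ, then the
smaller α (the more regularized model). Path fits inside the inner search
run at a relaxed tolerance of 1e-3 with a bounded sweep budget — the
out-of-fold deviance surface is insensitive at that level while strongly
correlated gene blocks would otherwise make the small-λ dense fits
needlessly expensive; every final per-fold refit uses the tight tolerance.

The nested scheme redoes *all* data-dependent choices inside each outer
training split: MAD-based top-200 gene selection, feature standardization
(training statistics applied to the held-out samples), and the inner
(α, λ) search. Outer and inner folds are stratified by class; the fold
draw is seeded and sample order is canonicalized so shuffling the input
columns cannot change the result. Pooled out-of-fold probabilities cover
every labeled sample exactly once and feed the ROC (trapezoidal AUC =
tie-corrected Mann–Whitney), the DeLong placement-value variance for
confidence intervals and paired model comparison, the Youden-J operating
point for reported sensitivity/specificity (the analysis convention when no
threshold is pre-specified), and a median split into risk groups with ties
going to the high side — with 123 distinct predictions that yields the
62/61 split used in group-size conventions.

## Survival analysis

Kaplan–Meier estimation, log-rank tests and Cox models delegate to the
`survival` package (Greenwood variance, log-log confidence bands, Efron tie
handling — appropriate for day-resolution data with moderate ties);
logistic alternatives use `glm`. The "time-to-progression, log odds-ratio"
wording for multivariate modeling is genuinely ambiguous between a Cox and
a logistic reading, so both are offered behind one `model` flag, defaulting
to Cox for time-to-event input. Wald inference comes from the inverse
information; unstable fits (possible separation, SE > 10³) are an error
with diagnostics. Harrell's c-index counts usable pairs (the earlier time
has an event) and is oriented so that values above 0.5 mean higher scores
go with worse survival; score ties count one half. The association map uses
Pearson correlation for continuous and 0/1-coded binary variables
(point-biserial) and Spearman for ordinal ones, with NA plus a warning for
constant variables.

## Cell-type-resolved scoring

Deconvolved expression arrives as per-patient, per-cell-type profiles.
Genes are z-scored jointly across *all* (patient, cell type) units after a
log1p — per-cell-type scaling would erase exactly the between-type
differences the percent-positive and progression analyses are about. The
per-cell scores used for percent-positive summaries are the mean z-score
of module genes per cell, a deliberate simplification of bin-matched
control-gene signature scoring; with a few hundred module genes the control
correction changes little and the simple mean keeps the per-cell path
dependency-free. Mann–Whitney progression tests run per cell type with Holm
adjustment across types; because it is not fully explicit whether the
p < 0.01 rule applies before or after adjustment, both flags are reported.

## The synthetic cohort generator

The generator is the package's study-condition definition, not a tuning
surface. Counts are negative binomial with variance $\mu + \mu^2\varphi$,
$\varphi = 0.5/\mu + 0.01$ — the standard decreasing mean-dispersion trend.
Gene baselines are uniform on the natural-log range $[\log 5, \log 500]$;
NB means are capped at a realistic library-depth ceiling (5×10⁶) so extreme
latent draws cannot overflow count storage. Module structure is additive on
the log-mean: gene loadings are half-normal with a floor of 0.25 (so every
planted gene carries a detectable share of its block's signal — a loading
arbitrarily close to zero would make "planted" meaningless), and latent
activities are N(0, 1) per patient × module × tissue, drawn independently
per tissue; membership and loadings are shared across tissues while mean
shifts (per-gene N(0, 0.5) tumor offsets) and activities are
tissue-specific.

A fraction (default 45/123, the cohort convention) of patients is
designated progression-prone; their TAN inflammatory-module activity is
raised by `inflammatory_effect` (default 1). Progression-free survival is
exponential with log-hazard `hazard_beta` per unit of the true TAN
inflammatory activity, with the baseline rate calibrated so an activity-0
patient has the designated event probability by the follow-up horizon
(8 years); censoring is administrative at the horizon plus an independent
Uniform(0, horizon) censoring time for a `censor_rate` fraction. The
default `hazard_beta = 1.5` was chosen once, from a latent-level
calibration of the discriminability of the planted signal (the AUC
attainable from the true activity), so that classifier power experiments
probe a clearly separable but not degenerate signal; the effect sizes of
the real inflammatory program are not reported in recoverable units, so
the defaults aim at testability, not fidelity.

Two subtleties matter for calibration tests. First, observed progression
*events* correlate with inflammatory activity whenever `hazard_beta > 0`,
even at `inflammatory_effect = 0`; true null checks therefore compare
against the *designated* prone group in the generator truth, which is
independent of expression under a zero effect. Second, the cell-type
emulation decomposes bulk TAN counts into profiles whose fraction-weighted
mixture reconstructs the bulk exactly (up to 5% log-normal noise), with the
designated cell type's affinity for inflammatory-module genes multiplied by
the planted elevation in prone patients — so the *designated-group*
contrast concentrates in that cell type, while event-based contrasts leak
into all types through the shared bulk signal, as they would in real
deconvolution output.

## Problem sizes and the recovery benchmark

The test suite and acceptance script run deliberately scaled-down
experiments chosen to keep each claim statistically meaningful: null and
power runs of the nested classifier at 200 patients × 2000 genes with
MAD-top-200 selection; module recovery at 80 patients × 600 genes in 20
planted blocks of 30; progression-ranking runs at 100 patients × 600 genes
over 100 seeds; Cox recovery at n = 1000 over 100 replicates. The recovery
benchmark enforces its 3:1 signal-to-noise premise for *every* planted
gene — activity SD 2.4 × loading floor 0.25 ≥ 3 × the ≈0.2 natural-log
residual SD measured on a signal-free cohort — and embeds in 20 principal
components: 20 mutually orthogonal block directions cannot be separated in
a 10-dimensional projection, so the embedding depth must reach the number
of planted blocks. The production default of 10 PCs remains the analysis
convention for real data, where modules are fewer than dimensions of
meaningful variation.

## What passing tests do and do not show

The generator emulates the statistical skeleton the pipeline assumes:
NB counts with a mean-dispersion trend, block-correlated modules, one
outcome-linked program, proportional-hazards survival. It does not emulate
read-level artifacts, batch effects, library-composition biases, UMI
structure, correlated module activities, non-proportional hazards, or the
empirical distributions of any real cohort. Green tests therefore certify
that the implementation detects what it claims to detect when that
structure is present, and stays calibrated when it is absent — they do not
certify effect sizes or error rates on real data. Cohort-scale headline
numbers (real-cohort AUCs, specific gene lists) depend on external data and
are out of scope by design.

## Numerical conventions

Variable-gene ties break lexicographically by gene ID; PAM ties by lowest
index; CV ties by larger λ then smaller α; risk-split ties go high.
Probabilities are clipped at 1e-12, IRLS weights at 1e-5 (the standard
guard against divergent working responses). Degenerate inputs fail loudly:
single-class labels, empty modules, non-positive survival times, k
exceeding the gene count, zero-variance features in correlation tests (NA
with warning). Exact Wilcoxon enumeration is limited to ≤10+10 tie-free
observations, matching the regime where exactness is affordable and the
normal approximation is weakest.
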