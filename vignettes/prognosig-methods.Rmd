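---
title: "Genomic aberration signatures and immune scores for ER+ breast cancer prognosis"
author: "PrognoSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic aberration signatures and immune scores for ER+ breast cancer prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PrognoSig)
```

# Motivation and model

Estrogen-receptor-positive (ER+) breast cancer has generally favorable
prognosis, but outcomes vary widely between patients. The premise of this
package is that recurrence risk is shaped by two kinds of features that can
both be read off a tumor's expression profile:

* **tumor-intrinsic features** — recurrent somatic driver events (gene
  mutations, amplifications, deletions) deregulate downstream pathways, and
  it is the downstream transcriptional state, not the mutation call itself,
  that carries prognostic information. Each recurrent event is therefore
  represented by a *weighted gene signature* learned from a cohort in which
  the event status is known, and every new tumor receives a continuous
  *signature score* measuring how strongly its expression resembles that of
  event carriers;
* **tumor-extrinsic features** — infiltration levels of six major immune
  cell types (naive B, memory B, CD4+ T, CD8+ T, NK cells, monocytes),
  scored from cell-type-specific reference expression profiles with the same
  enrichment statistic.

Signature, immune and clinical features are then combined in random-forest
classifiers of good versus poor prognosis and in Cox proportional-hazards
models of time to event.

## Aberration calling

A gene is a recurrent *mutation* event when at least one nonsynonymous
variant is observed in at least 10% of cohort samples (the bound is
inclusive: 10 carriers out of 100 qualify). Qualifying variant classes are
the nonsynonymous point-mutation classes plus, by default, frameshift and
in-frame indels (`includeIndels = TRUE`); multiple variants in the same
gene and sample count once.

Copy-number input is segment-level log2 ratios. Gene-level values are
overlap-length-weighted means of the overlapping segments (genes without any
overlapping segment are treated as copy-neutral, value 0). A gene is
*amplified* in a sample when its value exceeds `log2(2.82)` (about 1.496)
and *deleted* below `-log2(1.32)` (about -0.401); both bounds are plain
parameters, since the phrase "fold increase greater than log2(2.82)" in the
source literature admits a reading on the ratio scale as well — the literal
log2-ratio reading is the default. The same 10% recurrence bound is applied
to copy-number events; the literature states it only for mutations, and one
consistent default seemed preferable to a hidden asymmetry.

## Signature weights

With binary event indicators \(X_j\) and log2 expression \(Y_i\) (RNA-seq
input is transformed as \(\log_2(\mathrm{RSEM}+1)\) at load), every gene is
fit by ordinary least squares

\[ Y_i = \beta_{i,0} + \sum_j \beta_{i,j} X_j + \varepsilon_i , \]

either with all events jointly (*multivariate*, the form used for the
prognostic models, because it adjusts each signature for co-occurring
events) or one event at a time (*univariate*, used to show the scores
recapitulate the aberration status). The design matrix is shared by all
genes, so a single QR decomposition serves the whole matrix; p-values are
the usual two-sided coefficient t-tests. Genes with zero expression
variance get \(\beta = 0, p = 1\); a rank-deficient design is an error that
names the collinear events (with `dropCollinear = TRUE` to drop them).

The weights are sign-split and normalized per event: the raw weight of gene
i is \(-\log_{10} p_{i,j}\), assigned to the up-weight \(w^+\) when
\(\beta_{i,j} > 0\) and to the down-weight \(w^-\) when \(\beta_{i,j} < 0\)
(the other side is zero). Raw weights are capped at 10 and divided by the
range over the union of both capped vectors, so weights lie in \([0,1]\)
and any p-value at or below \(10^{-10}\) maps to weight 1. Base 10 is a
choice — the source describes \(-\log p\) without a base — exposed as
`logBase`; p-values are floored at `1e-300` before logging, which the cap
makes inconsequential.

## Sample scoring (rank-based enrichment)

For one sample, every gene is centered by its cohort median, genes are
ranked by decreasing signed centered value, and the magnitude \(g_k\) of the
k-th ranked gene is its absolute centered value. "Median normalization" is
implemented as this deregulation ranking rather than a ranking of raw
expression: raw ranks would reflect baseline transcript abundance, and the
cumulative-fraction construction below needs nonnegative magnitudes.

Foreground and background cumulative curves over the ranked profile,

\[ f(i) = \frac{\sum_{k \le i} g_k w_k}{\sum_k g_k w_k}, \qquad
   b(i) = \frac{\sum_{k \le i} g_k (1 - w_k)}{\sum_k g_k (1 - w_k)}, \]

are compared by the *signed* value of \(f - b\) at its largest absolute
excursion (a signed Kolmogorov–Smirnov-style deviation), computed separately
for \(w^+\) and \(w^-\). Each deviation is normalized against a permutation
null obtained by recomputing it under random orderings of \(g\) with the
weights fixed (1000 permutations by default), dividing by the mean absolute
null deviation; `nullNorm = "zscore"` instead centers and scales by the
null. The final score is normalized(Score\(^+\)) − normalized(Score\(^-\)):
positive when the sample's up-regulated genes are the carriers' up-regulated
genes and its down-regulated genes the carriers' down-regulated ones.

Numerical conventions worth stating:

* a constant weight vector makes \(f \equiv b\) algebraically; the
  implementation short-circuits this case to a deviation of exactly 0
  rather than leaving ~1e-16 floating-point residue;
* if \(\sum_k g_k w_k = 0\) (all relevant weights zero, or a flat profile)
  the score is defined as 0, with a warning when the whole weight set is
  zero;
* the statistic depends on \(g\) only through ratios, so rescaling all
  magnitudes by a positive constant leaves every curve and score unchanged;
* permutations come from a dedicated, seeded stream per sample
  (Fisher–Yates over a mt19937 generator in compiled code). By default the
  stream is shared by all weight sets scored for that sample, which makes
  identical weight sets score identically and costs one stream per sample;
  `sharePerms = FALSE` gives every (sample, weight set) pair its own
  stream.

## Immune infiltration scores

Reference profiles are cell types x genes on the log2 scale. The
specificity of gene i for cell type c is its reference expression in c minus
the maximum over the other types; the top 100 genes with positive
specificity (fewer, with a warning, if not enough exist) receive up-weights
proportional to specificity, scaled so the best marker has weight 1, and no
down-weights. Samples are then scored with the same enrichment statistic.
The underlying reference-profile method is reconstructed here from its
published description; scores are relative infiltration levels, not absolute
cell fractions, and no constrained-regression deconvolution is attempted.

## Prognosis models

**Labels.** With a 10-year horizon: an event at or before 10 years is
*poor* prognosis, follow-up beyond 10 years without an event (or an event
after the horizon) is *good*, and samples censored before 10 years carry no
label and are excluded.

**Random forests** (500 trees, \(\sqrt{p}\) features per split, Gini
importance; permutation importance available) are evaluated by stratified
10-fold cross-validation: out-of-fold class probabilities are pooled and
scored once for a single AUC. Stratification is a choice — the source
describes plain tenths — made to stabilize fold composition; samples are
put in a canonical lexicographic order first so fold assignment and the
pooled AUC do not depend on input row order. Backward elimination removes
exactly one least-important feature per step (ties broken alphabetically),
records the CV AUC at every set size, and selects the highest AUC at the
smallest feature count (AUC compared at 1e-4 resolution). Correlated ROC
curves are compared with DeLong's structural-components test.

**Cox models** use Efron tie handling (the standard default of the R
survival toolchain). Per-feature models are fit with and without the
clinical covariates (age, stage, grade, size, nodal count; grade and stage
enter as ordinal integers — the minimal assumption). Stepwise selection is
forward with backward checks on Wald p-values (enter/stay thresholds 0.15,
matching the documented defaults of the stepwise routine the source names),
with the clinical block optionally forced. Kaplan–Meier stratification uses
the median score (ties to the low group); predicted risk groups are
rank-based tertiles with remainder samples going to the lower groups.
Concordance counts a pair as comparable when both had events at different
times or one had an event before the other's censoring time, with tied
risks counted 1/2. "Removing the clinical features" from a fitted model is
implemented by zeroing their coefficients at prediction time
(`riskLinearPredictor(..., exclude = )`); refitting without them is the
configurable alternative, since either reading is defensible.

# The synthetic-cohort generator

Every downstream stage is exercised on simulated cohorts with planted
ground truth (`simulateCohort()`), because the cohorts the method was
developed on are access-controlled. The generator emulates:

* binary aberration status per event with **exact** carrier counts
  (`round(fraction * n)`), so recurrence boundaries are sharp;
* expression = gene baseline ~ N(7, 1.5) + additive event effects on
  disjoint planted gene sets (half the set up, half down, `effect` log2
  units, default 1.0 with 150-gene sets and 10–25% carrier fractions) +
  immune admixture + Gaussian noise (`noiseSd`, default 0.5 log2 units);
* immune admixture as reference profiles (disjoint marker sets, 60 markers
  per type by default, high in their own type only) weighted by per-sample
  Dirichlet fractions whose means match the configured infiltration levels;
* clinical covariates: age ~ N(60, 10), tumor size ~ log-normal,
  grade/stage ordinal multinomials, nodal count ~ Poisson;
* survival: exponential times with hazard \(h_0 \exp(\text{risk})\), where
  the risk combines planted event indicators, immune fractions and
  centered clinical variables (by default the first two events carry
  log-hazards 1.0 and 0.7 and memory-B infiltration is protective), and
  independent uniform censoring over `(0, horizon / censoringRate)` — the
  configured rate is an approximate target, not an exact quantile. All
  randomness flows from named substreams of one master seed.

`simulateGenomicFiles()` writes MAF/SEG/BED files whose re-called
aberration matrix equals the planted one exactly: mutation carriers get one
nonsynonymous MAF row each, copy-number carriers get segments beyond the
calling bounds exactly over the gene interval, and everything else stays in
a narrow neutral band (truncated N(0, 0.05)).

What the generator deliberately does **not** emulate: real gene–gene
correlation structure, probe-level artifacts, batch effects, subtype
structure, or the marginal distributions of any real cohort. Passing tests
therefore demonstrate that the implementation recovers what it plants under
its own assumptions — additive effects, proportional hazards, independent
censoring — not that the method attains any particular accuracy on real
tumors.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run at the sizes the methods
are designed for while staying desk-sized: cohorts of 400–600 samples with
1500–2000 genes and 1000-permutation scoring for end-to-end checks, smaller
fixtures for exact oracle comparisons (50-gene profiles against a plain
cumulative-sum reference implementation at 1e-12, OLS against explicit
normal equations at 1e-8, concordance against O(n²) pair enumeration).
`scripts/acceptance.R --seed <int> --out <path>` regenerates all headline
quantities from scratch; every random draw descends from the one seed.

# Known limitations

* Single-sample scoring needs a cohort (>= 2 samples) for median centering;
  scoring a lone sample would need an external reference median, which is
  not implemented.
* The univariate OLS p-values are equivalent to pooled-variance t-tests;
  no robust or moderated variance estimation is offered.
* Stepwise selection and backward elimination are greedy; they are the
  procedures specified, not optimal subset searches.
* No time-varying covariates, competing risks, or proportional-hazards
  diagnostics; no probability calibration of the forests.
* The comparator recurrence score (0–100, classes 0–17/18–30/31–100) is
  accepted as a precomputed input column; computing it from expression is
  out of scope.
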