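# PrognoSig

Tumor-intrinsic genomic-aberration signatures and tumor-extrinsic immune
infiltration scores for prognosis modeling in estrogen-receptor-positive
(ER+) breast cancer.

ER+ breast cancer has broadly favorable prognosis, yet individual outcomes
vary enough that genomic assays are used to guide treatment. Driver events
— recurrent gene mutations, amplifications and deletions — are themselves
only weakly prognostic, because many different lesions can deregulate the
same downstream pathway. PrognoSig implements the alternative: represent
each recurrent event by a **weighted gene signature** of its downstream
transcriptional consequences, score every tumor for how strongly its
expression resembles that of event carriers, add immune-infiltration scores
for six cell types, and feed these continuous features into random-forest
and Cox proportional-hazards models of recurrence risk. The package is
aimed at computational biologists who want to reproduce or extend this
class of expression-based prognostic models.

## The model in brief

1. **Aberration calling.** Mutation events: genes with ≥1 nonsynonymous
   variant in ≥10% of samples (MAF input). Copy-number events: gene-level
   log2 ratios (overlap-weighted means over SEG segments) above
   `log2(2.82)` (amplification) or below `-log2(1.32)` (deletion), at the
   same recurrence bound.
2. **Signature weights.** For every gene *i*, OLS of log2 expression on
   the binary event indicators, jointly (multivariate) or one at a time
   (univariate):

   *Y<sub>i</sub>* = β<sub>i,0</sub> + Σ<sub>j</sub> β<sub>i,j</sub> X<sub>j</sub> + ε.

   Per event *j*: w⁺<sub>i</sub> = −log₁₀ p<sub>i,j</sub> if
   β<sub>i,j</sub> > 0, w⁻<sub>i</sub> = −log₁₀ p<sub>i,j</sub> if
   β<sub>i,j</sub> < 0, capped at 10 and divided by the range, so weights
   lie in [0, 1].
3. **Scoring.** Per sample, genes are median-centered against the cohort
   and ranked by signed deregulation; foreground f(i) and background b(i)
   cumulative curves over the ranked magnitudes are compared by their
   signed maximum deviation, separately for w⁺ and w⁻, each normalized by
   a 1000-permutation null; score = normalized(Score⁺) −
   normalized(Score⁻).
4. **Immune scores.** Marker weights from cell-type-specific reference
   profiles (specificity = own-type expression minus the best other type,
   top 100 positive genes), scored with the same statistic.
5. **Prognosis.** 10-year good/poor labels (censored-before-horizon
   excluded); stratified 10-fold cross-validated random forests with pooled
   out-of-fold AUC, DeLong tests between correlated ROC curves, backward
   feature elimination; univariate/clinically-adjusted/stepwise Cox models,
   Kaplan–Meier + log-rank stratification, concordance index, tertile risk
   groups.

A synthetic-cohort generator (`simulateCohort()`) plants all of this
structure — carriers, signature gene sets, immune admixture, clinical
covariates, exponential survival — so the whole pipeline is testable
without access-controlled patient data, including exact round-trips through
written MAF/SEG/BED files.

## Worked example

```r
library(PrognoSig)

cfg <- simulationConfig(nSamples = 120, nGenes = 600,
    events = data.frame(label = c("TP53_mut", "CCND1_amp"),
                        fraction = c(0.20, 0.15), setSize = 60L, effect = 1.0),
    immune = data.frame(cellType = IMMUNE_CELL_TYPES,
                        meanFraction = rep(0.04, 6), markerSize = 20L),
    seed = 42)
coh <- simulateCohort(cfg)
coh
#> ProgCohort: 600 genes x 120 samples
#>   aberration events: 2
#>   colData: age, stage, grade, size, nodes, time, event
#>   with simulation ground truth

uni <- fitSignatures(coh, mode = "univariate")
uni$weights[["TP53_mut"]]
#> SignatureWeightSet 'TP53_mut': 600 genes, 310 up / 290 down weights

sc <- scoreCohort(coh, uni$weights, nPerm = 1000, seed = 7)
round(head(sc[, "TP53_mut"], 3), 3)
#>  S0001  S0002  S0003
#> -2.252 -2.171  2.428

status <- aberrations(coh)[, "TP53_mut"]
aucScore(sc[, "TP53_mut"], status)
#> [1] 0.995

surv <- survivalData(coh)
coxFit(data.frame(TP53_sig = sc[, "TP53_mut"]), surv$time, surv$event)
#> Cox model: 120 samples, 75 events; concordance = 0.645
#>           coef   hr     se   z        p
#> TP53_sig 0.275 1.32 0.0572 4.8 1.55e-06
```

The TP53-like signature score separates planted carriers from
non-carriers almost perfectly (AUC 0.995) and, because carrier status was
planted into the simulated hazard, the score is strongly associated with
survival (hazard ratio 1.32 per score unit, p ≈ 2e-6). `runAll()` runs the
same stages end to end on a cohort and writes weight/score TSVs plus JSON
classification and survival reports; `inst/scripts/prognosig.R` wraps the
exported functions for shell use.

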