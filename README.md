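# pacsense

Predicting who benefits from second-line paclitaxel in advanced gastric
cancer (AGC), from integrated clinical and genomic features.

After first-line fluoropyrimidine/platinum chemotherapy fails, the decision
to give vulnerable AGC patients second-line paclitaxel (usually with
ramucirumab) has no established predictive biomarker. `pacsense` implements,
as a tested and reusable R pipeline, a study design that attacks this
problem with machine learning on panel-sequencing data: patients are
labelled *paclitaxel-sensitive* (progression-free survival, PFS, beyond 6
months) or *paclitaxel-resistant* (progression before 3 months), split
80:20 with outcome stratification, and classified from binary clinical
covariates plus pathogenic variants by four models — random forest (RF),
logistic regression (LR), a feed-forward artificial neural network (ANN),
and an ANN with a **learned genetic embedding** (ANN with GE). Predicted
strata are then validated on raw survival endpoints with Kaplan–Meier
curves and the log-rank test.

Because the motivating cohort is not publicly available, the package ships
a calibrated synthetic-cohort generator as a first-class module: binary
clinical covariates with realistic prevalences, a panel of 73 SNVs and 29
CNVs over 87 genes, exponential survival anchored to the printed medians
(PFS 2.70 months, OS 13.28 months), and a *planted* benefit signal that may
include purely non-additive (epistatic) variant interactions — the regime
in which a learned variant-set embedding should outperform a linear model.

## The core model

Each panel variant `v` owns a learned embedding row `E[v, ] ∈ R^d`
(d = 20). A patient carrying the variant set `S` is represented by the
aggregated genetic feature

    g(S) = agg_{v ∈ S} E[v, ]        (mean or sum; empty set -> 0)

concatenated with k = 6 binary clinical features
(young-onset age, male sex, intestinal histology, prior trastuzumab,
first-line duration < 3 / ≥ 6 months), and classified by a single hidden
layer of h = 20 rectified units:

    p = sigmoid( w2 · relu(W1' [x_clin, g(S)] + b1) + b2 )

Embeddings and network weights are trained jointly by minibatch Adam on the
binary cross-entropy; `g(S)` is invariant to the order and multiplicity of
the variant list, and embedding rows of variants never seen in training
remain exactly at their initialisation. The three baselines (RF, ridge LR,
plain ANN on the binary `k + V` vector) sit behind the same seeded
fit/predict contract. Kaplan–Meier estimation, median survival, the
log-rank test, ROC/AUROC (Mann–Whitney mid-rank ties) and stratified
percentile bootstrap confidence intervals are implemented from first
principles and cross-checked in the tests against independent oracles and
the `survival` package.

## Worked example

Simulate a cohort of 2,000 patients whose benefit signal is pure epistasis
(two balanced four-cycles of pairwise variant interactions, coefficient
±1.5, with *zero* additive variant effects — invisible to a main-effects
model), then run the full experiment for LR and the embedding network:

```r
library(pacsense)

cycle <- function(v, g)
  cbind(c(v[1], v[3], v[1], v[2]), c(v[2], v[4], v[3], v[4]), c(g, g, -g, -g))
effect <- effectSpec(102, gammaPairs = rbind(cycle(1:4, 1.5), cycle(5:8, 1.5)))
prev <- rep(0.08, 102); prev[1:8] <- 0.3

cfg <- experimentConfig(
  cohortConfig(nPatients = 2000, variantPrevalences = prev, effect = effect,
               censoringRate = 0.1, seed = 1),
  models = list(
    logistic_regression = modelSpec("logistic_regression", seed = 1),
    ann_with_ge = modelSpec("ann_with_ge", aggregation = "sum",
                            learning_rate = 0.01, monitor = "auc", seed = 1)),
  nBoot = 1000L, seed = 1, outDir = "results")
report <- runExperiment(cfg)
```

The written `summary.txt` reads:

```
pacsense experiment summary
  seed 1; 2000 patients (1617 labelled: 1293 train / 324 validation)
  vocabulary: 102 variants (train_only policy)

model logistic_regression
  training   AUROC 0.659 (95% CI 0.630-0.693)
  validation AUROC 0.500 (95% CI 0.429-0.567); sens 0.129 spec 0.933 acc 0.682 F1 0.202
  validation PFS median 2.47 vs 1.57 months, log-rank p 0.0355
  validation OS  median 18.65 vs 13.82 months, log-rank p 0.4759
model ann_with_ge
  training   AUROC 0.975 (95% CI 0.964-0.985)
  validation AUROC 0.565 (95% CI 0.496-0.629); sens 0.327 spec 0.744 acc 0.614 F1 0.346
  validation PFS median 2.20 vs 1.43 months, log-rank p 0.0068
  validation OS  median 16.34 vs 13.18 months, log-rank p 0.0474
```

Read: the ridge LR generalises at chance (validation AUROC 0.500) because
the planted signal has no additive projection, while the embedding network
recovers part of it (0.565) and is the only model whose predicted-sensitive
stratum shows significantly longer PFS (p = 0.0068) *and* OS (p = 0.047)
in the held-out patients — survival curves the model never saw as such,
since it was trained on thresholded labels only. Medians per predicted
group, at-risk tables and ROC points are written as CSV next to the
summary.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end experiment from scratch — simulating
the planted-epistasis cohort, training all four classifiers, evaluating
validation AUROCs with bootstrap confidence intervals and the
predicted-strata log-rank tests — logging a per-model summary and writing
the acceptance JSON to `--out`.

## Package tour

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `cohortConfig`, `effectSpec`, `generateCohort`, `benefitScore`, `sampleSurvival`, `writePatientCSV`, `writeVariantCSV`, `loadCohort` |
| Features & labels | `assignLabel`, `buildClinicalFeatures`, `buildVariantVocabulary`, `buildVariantMatrix`, `buildFeatureSet`, `stratifiedSplit` |
| Baseline tables | `summarizeCohort`, `categoricalBalanceTest`, `writeBaselineTable`, `pctOf` |
| Models | `modelSpec`, `fitClassifier`, `predictProba`, `trainEmbedNet`, `embedAggregate`, `forwardEmbedNet`, `saveModel`/`loadModel` |
| Evaluation | `auroc`, `rocCurve`, `bootstrapAurocCI`, `thresholdMetrics` |
| Survival | `kmEstimate`, `kmMedian`, `logrankTest`, `comparePredictedGroups`, `writeSurvivalCSV` |
| Orchestration | `experimentConfig`, `runExperiment`, `writeReport` |

The methods vignette (`vignettes/paclitaxel-benefit-modelling.Rmd`)
documents the generative model, every tunable parameter with its default
and rationale, the numerical choices, and what a green synthetic-data test
does — and does not — establish.
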