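# octenrich

Predicting suboptimal anatomical response to the aflibercept loading-phase
in neovascular age-related macular degeneration (nAMD), and evaluating what
that prediction buys a clinical trial.

Exudative nAMD is treated with three monthly intravitreal anti-VEGF
injections (the loading-phase). Response is heterogeneous: a substantial
fraction of eyes still shows intra- or subretinal fluid on OCT at the
follow-up visit ("suboptimal responders", outcome 1). Identifying those
eyes *at baseline* — from the OCT raster volume plus routine clinical
features — would let trials of novel agents enrich their cohorts with the
patients most likely to need them. `octenrich` implements that multi-modal
prediction pipeline end to end, together with a synthetic-data generator so
that every stage is testable without any patient data.

The package is aimed at methodologists in ophthalmic imaging and at anyone
studying predictive enrichment of trial cohorts.

## What is inside

**Cohort handling.** Eyes are assigned to a *standard* protocol (therapy
course 105–135 d, last-injection-to-observation gap 49–70 d) or a *short*
protocol (75–104 d, gap 21–48 d); everything else is excluded. Splits are
drawn at the patient level, stratified by protocol, outcome and scan count,
with a 20% test set and 20% of the remainder for validation; training sets
are further cut into five folds stratified by clinic and outcome.

**Pre-processing.** Each B-scan is bilinearly resized to 200 × 300; the
stack is subsampled (or evenly duplicated) to 20 scans via
idx<sub>k</sub> = round(k·(n−1)/19); the resulting 20 × 200 × 300 matrix is
rescaled so its 1st/99th intensity percentiles map to −1/+1. Clinical
features are standardised with training-set statistics only (CST on the log
scale), missing values imputed by 0 after standardisation, sex and clinic
one-hot encoded.

**Image operators.** Single-level Daubechies-1 (Haar) decomposition turned
into an edge map |LH|+|HL|+|HH|; composite retinal foreground detection
(per column, a significant wavelet edge — ≥ 2 SD above the edge-map mean —
OR luminosity surpassing a column threshold regressed 50% towards the image
mean, scaled by tunable multipliers); background zeroing; per-volume affine
augmentation (rotation ±20°, translation ±10 px, horizontal flip, scale
0.8–1.5) applied identically to all scans.

**Models.** Three families score each eye in [0, 1]:

* a CNN — either a *2.5D* residual network (one shared 2D backbone applied
  per scan, features averaged across scans, hence invariant to scan order)
  or a *3D* six-convolutional-layer network — trained with Adam on
  cross-entropy for up to 100 epochs, keeping the weights of the epoch with
  the best held-out-fold AUROC;
* an L1-regularised logistic regression on 2D-FFT magnitudes reduced by 85%
  to the training-dominant frequencies, each scan carrying its volume's
  label, volume score = mean scan score;
* an L2-regularised logistic regression on the clinical features.

Scores are stacked by a ridge logistic ensemble; greedy forward selection
on validation AUROC decides which models enter. Transfer retraining
initialises a short-protocol CNN from the standard-protocol weights.

**Evaluation & enrichment.** AUROC (rank statistic, tie credit ½) with
stratified percentile-bootstrap 95% CIs; sensitivity/specificity at 90%
operating points; Fisher / Mann–Whitney univariate associations with
Benjamini–Hochberg FDR; odds ratios with Pearson χ². Trial selection is
emulated by taking the top-k eyes per method (model score ↓, CST ↓, age ↑,
or random), counting suboptimal responders, and reporting the AI method's
percent increase over the best alternative and over random selection.

## Worked example

```r
library(octenrich)

cohort <- generate_synthetic_cohort(cohort_config(n_patients = 800, seed = 11))
kept   <- apply_exclusions(cohort)$kept
table(kept$protocol, kept$outcome)
#>              0   1
#>   short    170  99
#>   standard 247 337

splits <- split_cohort(kept, seed = 11)
std    <- merge(kept[kept$protocol == "standard", ],
                splits[, c("eye_id", "partition")])
train  <- std$partition == "train"

feats <- normalize_clinical(std, std$eye_id[train])
model <- fit_clinical_logreg(feats$x[train, ], std$outcome[train])
coef_ranking(model)
#>        age    log_cst sex_female        trv va_letters
#>      0.384      0.344      0.071      0.062      0.004

test  <- std$partition == "test"
score <- predict(model, feats$x[test, , drop = FALSE])
auroc_with_ci(score, std$outcome[test], seed = 1)
#> $auroc
#> [1] 0.6914408
#> $ci
#> [1] 0.5927429 0.7804066

tab <- build_enrichment_table(std[test, ], setNames(score, std$eye_id[test]),
                              sizes = c(20, 50, 100))
print(tab, digits = 3)
#>   cohort_size   ai  cst  age random pct_increase_vs_alt pct_increase_vs_random
#> 1          20 0.85 0.70 0.80  0.578                6.25                  47.16
#> 2          50 0.74 0.72 0.66  0.578                2.78                  28.12
#> 3         100 0.62 0.60 0.61  0.578                1.64                   7.34
```

Reading the output: in this simulated standard-protocol cohort, 337/584 eyes
(58%) retain fluid; the clinical model ranks age and log-CST as the
strongest baseline predictors and separates responders with AUROC 0.69
[0.59, 0.78] on the held-out test set. Selecting a hypothetical 20-eye trial
by model score yields 85% suboptimal responders versus 57.8% under random
selection — a 47% relative increase.

The image side works the same way: `generate_oct_volume()` produces phantom
B-scan volumes (with ground-truth band boundaries), `preprocess_volume()`
standardises them, and `build_cnn()` / `train_image_model()` /
`fit_fft_lasso()` produce volume scores that `fit_stacker()` combines with
the clinical score.

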