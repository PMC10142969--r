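---
title: "Methods: multi-modal response prediction and trial enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal response prediction and trial enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models and
procedures, the parameters that matter, the numerical choices made where a
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## The problem

An eye with exudative neovascular AMD receives three monthly aflibercept
injections; at the follow-up visit its OCT volume either shows residual
intra-/subretinal fluid (outcome 1, a *suboptimal responder*) or is dry
(outcome 0). The task is to predict that binary outcome from baseline data
only — the OCT raster volume and a handful of clinical features (age, sex,
ETDRS letters, central subfield thickness CST, total retinal volume TRV) —
and then to quantify how much a score-ranked candidate selection enriches a
hypothetical trial cohort with suboptimal responders.

Observation timing matters: eyes observed ~8 weeks after the third
injection (therapy course 105–135 d, gap 49–70 d) form the *standard*
protocol subcohort; eyes observed ~4 weeks after it (course 75–104 d, gap
21–48 d) form the *short* protocol subcohort. Dryness is substantially more
frequent under the short protocol, so all modelling is per protocol. The
gap windows deserve a note: "about 8 weeks" and "about 4 weeks" are not
sharp definitions, so the package uses [49, 70] and [21, 48] days — wide
enough to cover observed timing spreads of 58 ± 3 and 32 ± 6 days without
overlapping each other.

## The synthetic-data generator

No public dataset exists for this problem, so the generator is a
first-class module: it defines the study conditions every other module is
tested under.

**Clinical cohorts** (`generate_synthetic_cohort()`). Patients carry age ~
N(80, 8²) years truncated to [50, 100], female sex with probability 0.62,
a 10-level clinic label, and per-eye CST ~ logNormal(log 350, 0.25²) µm,
TRV ~ N(9.5, 1.5²) mm³, ETDRS letters ~ N(58, 13²). A patient contributes
a second eye with probability 0.067. Outcomes follow a logistic model on
standardised age, female sex, and standardised log-CST with configurable
coefficients; the defaults (−0.5, −0.35, +0.5 log-odds) reproduce the
directions and rough magnitudes of the real cohort's univariate contrasts
(older age and female sex protective, thicker maculae harmful). The
intercept is not a free parameter: it is solved by bisection, per protocol,
so that the mean predicted probability over the realised covariates equals
the configured prevalence (defaults 0.593 standard, 0.375 short). This
decouples effect sizes from prevalence — raising an effect never silently
shifts the base rate. Therapy-course and gap lengths are drawn from
N(117, 6²)/N(58, 3²) (standard) and N(91, 6²)/N(32, 6²) (short), clamped
to the protocol windows, so the protocol classifier is exercised on
realistic spreads.

**OCT phantoms** (`generate_oct_volume()`). Each B-scan holds a smooth
two-boundary band — base intensity 0.45–0.80 with a layered sinusoidal
texture and a bright top line at 0.9, emulating the inner limiting
membrane — over a 0.05 background, with sinusoidal undulation across
columns and a slow tilt across scans. Fluid, when requested, is a set of
dark ellipsoids strictly inside the band, spanning contiguous scans, with
intensity reduced by `fluid_contrast`. Gaussian noise is added last,
without clipping. This is deliberately the simplest structure that
exercises foreground detection (a band with known per-column boundaries,
which the generator emits as ground truth) and fluid classification (a
local, dark, in-band feature). It does **not** emulate OCT speckle
statistics, MNV subtypes, pigment epithelial detachments, vessel shadows,
or segmentation artefacts — so passing tests demonstrate that the
*algorithms* behave as specified, not that the trained networks would
transfer to real Spectralis scans. Native phantom size defaults to
320 × 384 (a scaled-down Spectralis geometry); tests use smaller sizes
still, which only changes compute, not structure.

## Pre-processing

The volume pipeline is: per-scan bilinear resize to 200 × 300 (in volume
order), subsampling to 20 scans with idx_k = round(k·(n−1)/19) for
k = 0..19 (half-up rounding, so the formula is reproducible across
platforms; duplicates spread evenly when n < 20), then one linear intensity
map taking the empirical 1st/99th percentiles of the *final* 20 × 200 × 300
matrix to −1/+1. Three details were open and are fixed as follows:

* percentile estimator: linear-interpolated empirical percentile
  (`quantile type 7`) over all voxels;
* values beyond the percentiles are *not* clipped — only the two anchor
  points are specified;
* percentiles are computed after subsampling, on the matrix the model
  actually sees.

Clinical features use training-set mean/SD only (unbiased n−1 SD, the
feature-scaling convention), log-CST instead of CST (strictly positive,
right-skewed), imputation by 0 *after* standardisation with an explicit
imputation mask, a female-sex indicator, and clinic one-hot columns over
training-seen clinics (unseen clinics become the all-zero reference).
Nothing from validation or test rows can influence the statistics; the test
suite asserts this by perturbing held-out rows.

## Image operators

**Edges.** "Edges" are the single-level Daubechies-1 detail magnitudes
|LH| + |HL| + |HH|, replicated 2 × 2 back to input resolution so the matrix
size is unchanged, then standardised to mean 0, SD 1. The orthonormal Haar
filters make the decomposition energy-conserving, which the suite checks
(Parseval to 1e−10).

**Foreground.** Per column, the top of tissue is the first row where the
wavelet edge is significant (≥ 2 SD above the edge-map mean, statistics per
scan — the detection is described per image, so no cross-scan pooling) OR
the intensity strictly surpasses a luminosity threshold: the column
statistic regressed 50% towards the whole-image statistic, times a tunable
multiplier. The bottom uses the intensity criterion alone (no sharp edge
borders the choroid). Two guards matter in degenerate cases: the edge
criterion is disabled when the edge map is constant (SD 0), and
"surpasses" is strict — otherwise an all-zero scan would come out
all-foreground instead of all-background. The luminosity statistic defaults
to the mean with a percentile override, and the multipliers default to 1.5;
on phantoms this recovers the true top boundary within 3 px for >99% of
columns, and the multipliers are exposed as the "background level"
hyperparameter of model training. Background pixels are then set exactly
to 0; on percentile-normalised volumes the luminosity statistics are
computed on a copy shifted to a zero minimum, since the criterion is meant
for non-negative intensities.

**Augmentation.** One affine map per volume — flip, then scale (zoom in up
to 50%, out up to 20%), then rotation (±20°), then translation (±10 px per
axis) — composed into a single matrix about the image centre and applied
identically to all scans with bilinear interpolation and zero fill.
Coordinates place the centre of pixel *i* at *i* − 0.5; the test suite pins
the exact convention against an independent from-scratch resampler.

## Models

No deep-learning framework is involved: the convolutional networks are a
compact, fully tested base-R implementation (im2col convolutions, exact
backpropagation, Adam) whose width and depth are configurable, so the
architectures run at desk scale. The published final hyperparameters are
the defaults of `training_config()` — 2.5D network on wavelet input, batch
4, learning rate 3.4e−6, weight decay 0.036, dropout 0.24, up to 100
epochs — while tests use shrunken backbones and larger learning rates
suited to phantom tasks.

* **2.5D residual network**: a shared 2D backbone (stride-2 stem, stride-2
  reduction, n residual blocks) runs on every scan; per-scan global-average
  features are averaged across scans before a sigmoid head. Scan-order
  invariance is structural and tested to 1e−5.
* **3D network**: six 3D convolutional layers with stride-based
  downsampling, global average pooling, sigmoid head.
* Training selects the epoch with the best held-out-fold AUROC. Ties go to
  the *latest* tying epoch: with a small held-out fold the AUROC takes few
  distinct values, and at equal held-out performance the longer-trained
  weights are preferred. Dropout acts on the pooled feature vector; weight
  decay is an L2 gradient penalty on weights (not biases); cross-entropy is
  unweighted (no class weighting is specified for the original pipeline).
  One seed fixes initialisation, data order, dropout and augmentation, and
  the suite asserts bit-identical retraining.
* **FFT + lasso**: per-scan 2D FFT magnitudes, reduced by 85% to the
  coefficients with the largest magnitude *averaged over training scans*
  ("dominance" needed a definition; the training-mean ranking is the
  simplest leakage-free one), then an L1 logistic regression with every
  scan inheriting its volume's label. CV folds keep whole volumes together
  so scans of one eye never straddle a fold. Volume score = mean scan
  score.
* **Clinical model**: ridge logistic regression on the normalised feature
  matrix (already standardised, so glmnet's internal standardisation is
  off and absolute coefficients are comparable), λ tuned by 5-fold CV.
* **Transfer retraining**: the short-protocol CNN starts from the
  standard-protocol weights with all layers trainable and the same
  epoch-selection rule; zero epochs returns the source weights unchanged.
* **Hyperparameter search**: uniform/log-uniform sampling with a fixed
  trial sequence per seed; the evaluation function is supplied by the
  caller (train + validation AUROC in production, cheap surrogates in
  tests), and the full trial log is returned.

## Ensemble

The stacker is an L2 logistic regression on the raw [0, 1] score columns
(no logit transform — the scores are used as given), λ tuned by 5-fold CV;
it is implemented by direct penalised optimisation so that single-column
stacks are possible. Forward selection greedily adds the candidate whose
stacker most improves validation AUROC and stops when no candidate adds
more than 1e−4 (a strict-improvement threshold had to be chosen; 1e−4 is
below any meaningful AUROC difference at realistic test sizes). Ties break
by the fixed candidate order (cnn, clinical, fft_lasso). The short-protocol
ensemble reuses the standard-protocol selection rather than re-running it,
and the stacker is fitted on training scores in both cases.

## Evaluation

AUROC is the Mann–Whitney rank statistic with half credit for ties,
verified against an O(n²) pair-enumeration oracle. Confidence intervals are
class-stratified percentile bootstrap (2000 replicates, seeded) — the CI
method was unspecified, and the stratified percentile bootstrap is the
standard assumption-light choice. Operating points pick the least stringent
cutoff achieving the 90% sensitivity (or specificity) target; because a
threshold chosen on the evaluation data itself need not generalise, a
pre-fixed threshold (e.g. chosen on validation) can be supplied instead —
both modes exist. Univariate associations use two-sided Fisher exact tests
for binary features and Mann–Whitney U for continuous ones, with BH-FDR
across the tested family; constant features are skipped and excluded from
the family. The 2 × 2 odds ratio uses the Pearson χ² without continuity
correction, with the Haldane–Anscombe 0.5 correction (flagged) for zero
cells.

## Enrichment emulation

Candidates are *eyes* (the published table counts eyes, and some patients
contribute two), selected by ensemble score descending, CST descending,
age ascending, or at random, with ties broken by eye id. The random
column is reported as the analytic expectation — the test-set prevalence,
constant across trial sizes, which is what a constant published random
column implies — with a seeded Monte-Carlo mode as an alternative. The two
derived columns are 100·(f_AI − max f_alt)/max f_alt against the best
non-random alternative at that size, and 100·(f_AI − f_rand)/f_rand
against random; both recompute exactly from the stored fractions.

## Problem sizes and determinism

The test suite and the acceptance script run everything at sizes chosen to
exercise structure rather than scale: phantom volumes of 6–20 scans at
24 × 32 to 120 × 150 for model training and foreground checks (full
20 × 200 × 300 volumes are used where the contract is about shape),
cohorts of 50–10 000 patients depending on the statistical precision a
check needs, CNN backbones of 3–8 channels and one residual block, and
5–16 training epochs at learning rates around 1e−2 appropriate for those
tiny tasks. Every stochastic step takes an explicit integer seed, and
seeded byte-identical reproducibility is itself a tested contract.

## Known limitations

* The phantom generator's simplicity means image-model performance on
  phantoms says nothing quantitative about real-data AUROC; only the
  pipeline mechanics and leakage discipline are validated.
* Real acquisition variability (differing per-clinic scan protocols,
  device intensity scales) is reduced to a scan-count mix and per-volume
  percentile normalisation.
* Per-clinic protocol mixes are unknown; clinics are a uniform categorical
  in the generator.
* The residual backbone is depth-configurable rather than a fixed 50-layer
  network, and no ImageNet pretraining is assumed (whether the original
  used it is unstated); transfer retraining is therefore demonstrated
  between synthetic subcohorts, not from natural images.
* Human grading steps (MNV verification, segmentation correction, foveal
  re-centring) are out of scope and not automated.
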