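---
title: "Standardizing tES dose from accessible predictors: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing tES dose from accessible predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesdose)
```

## The problem

Transcranial electrical stimulation (tES) delivers a weak current (typically
1–4 mA) through scalp electrodes. The electric field (E-field) this induces
in the brain varies strongly between people — by up to a factor of two for
an identical current — because skulls, cerebrospinal-fluid layers and head
geometries differ. A fixed current therefore delivers an inconsistent
*dose*. The precise remedy, per-participant finite-element E-field
simulation from structural MRI, is accurate but expensive and inaccessible
to most laboratories and clinics.

`tesdose` implements the accessible alternative: regression models that
predict each individual's **peak E-field strength** (the 95th percentile of
the E-field magnitude over grey-matter voxels at a 1 mA reference current)
from predictors obtainable with a tape measure and an intake questionnaire —
age, gender, head circumference, cephalic index, BMI and, for
montage-agnostic models, the inter-electrode distance. The predicted field
then sets an individualized current so that everyone receives the same
target dose.

## The models

All predictors are standardized by rules matched to their distributions:
min–max scaling for age (approximately uniform in an adult lifespan
cohort), z-scoring for head circumference, cephalic index and the
per-montage peak E-field, median/IQR scaling for the right-skewed BMI, and
a 1 (male) / 0 (female) encoding for gender. Standardization parameters are
always estimated on training data only and travel with the fitted model.

**Montage-specific model.** For a fixed electrode montage, the
standardized peak E-field is a linear function of the five standardized
predictors,

$$E_{MS} = \beta_1 x_{age} + \beta_2 x_{HC} + \beta_3 x_{CI} +
\beta_4 x_{BMI} + \beta_5 x_{gender} + \beta_0,$$

fit by iteratively reweighted least squares (IRLS) with Tukey's bisquare
weight, tuning constant $k = 4.685$ (approximately 95% Gaussian
efficiency). Robustness matters because simulated E-field datasets contain
occasional gross outliers from meshing defects. Multicollinearity is
screened with variance inflation factors; values below 2.5 are considered
acceptable, and exceedance warns rather than aborts.

**Montage-agnostic models.** To generalize to montages absent from the
training data, per-montage coefficient vectors are averaged
($\bar\beta$) and the prediction is scaled by a function of the
inter-electrode distance $x_{ED}$ (the anode–cathode midpoint distance;
for high-definition (HD) montages, the mean of the four anode–return
distances). Two variants are provided, one linear and one quadratic in
distance:

$$E_{LMA} = (S\,x_{ED}) \times (\bar\beta_1 x_{age} + \cdots +
\bar\beta_6 x_{ED} + \bar\beta_0), \qquad
E_{NMA} = (S_1 x_{ED}^2 + S_2 x_{ED} + S_3) \times
(\bar\beta_1 x_{age} + \cdots + \bar\beta_0).$$

The linear variant's inner term carries a (standardized) distance
coefficient; the quadratic variant's inner term does not — the two printed
forms are implemented exactly as written. Per-montage models for the
linear variant are therefore fit with six predictors before averaging,
those for the quadratic variant with five.

**Dosing.** At tES intensities the induced field is linear in the applied
current, so the individualized current is
$I = I_{applied} / E_{generated} \times E_{target}$. The comparison
baseline is *fixed dosing*: one common current chosen so the population
mean realized field equals the target. Dose standardization helps exactly
to the extent the model explains variance: if the model attains $R^2 =
\rho^2$ out of sample, a first-order (delta-method) argument gives a
population SD reduction of $1 - \sqrt{1 - \rho^2}$, which the test suite
verifies by Monte Carlo at $\rho^2 \in \{0.2, 0.43, 0.6\}$.

## Estimation choices worth knowing

These points were genuinely open in the procedure and were decided once,
as follows.

* **IRLS details.** Scale is re-estimated each iteration as
  $\mathrm{median}(|r|)/0.6745$; residuals are studentized by
  $\sqrt{1-h}$ using design leverages $h$; initialization is OLS;
  convergence is a maximum absolute coefficient change below $10^{-8}$,
  capped at 50 iterations. These are the de-facto standard choices of
  mainstream robust-fitting routines, and the test suite pins the
  implementation against an independent robust fitter (`MASS::rlm`,
  agreement to $10^{-4}$ on contaminated data) and against OLS in the
  $k \to \infty$ limit (agreement $10^{-6}$).
* **Two-stage agnostic estimation.** The scaling coefficients $S$ are
  estimated by ordinary least squares *with $\bar\beta$ frozen* (the
  model is linear in $S$ given the inner term). The workflow fixes
  $\bar\beta$ by averaging first; the intercept is not refit after
  averaging.
* **Raw vs standardized distance.** The scaling factor uses the raw
  distance in mm: a z-scored distance can be negative and would flip the
  sign of the prediction, which is physically meaningless. The inner-term
  distance coefficient $\bar\beta_6$ uses the standardized distance,
  consistent with the other features.
* **Outcome standardization for pooling.** Peak E-fields are z-scored per
  montage with training-fold statistics before agnostic pooling; pooling
  raw scales would let the montage-level field scale enter both the
  outcome and the distance term.
* **Degenerate distance columns.** When a montage's inter-electrode
  distance is constant across training rows (e.g. template-level
  distances), the stage-1 distance coefficient is unidentifiable — it is
  dropped and reported as 0 rather than producing a singular fit.
* **Fences and percentiles.** Percentiles and quartiles use the
  linear-interpolation convention (type 7). The per-montage QC rule
  rejects values outside Tukey fences $[Q_1 - 3\,\mathrm{IQR},\;
  Q_3 + 3\,\mathrm{IQR}]$; a median-centered alternative is selectable
  because the verbal form of the rule is ambiguous. Every report embeds
  these convention choices.
* **NRMSE normalizer** defaults to the mean of the observed outcomes
  (range-normalization selectable); computed on the V/m scale so the
  normalizer cannot vanish.
* **Levene center** defaults to the median (Brown–Forsythe), robust for
  the heavy-tailed realized-dose distributions; the classic mean-centered
  test is selectable. Type-I error calibration at $\alpha = 0.05$ is
  verified by 2000 null simulations.
* **Test-set adjusted $R^2$** uses the evaluation set's own mean in the
  total sum of squares.
* **Age extrapolation.** Ages outside the training range extrapolate
  linearly; clipping would silently distort the dose for elderly
  participants, the riskiest extrapolation regime.
* **Safety cap.** Individualized currents are clipped at a configurable
  4 mA cap *with a flag* — the evaluation protocol itself applies no cap,
  but a deployment interface should never silently emit a huge current
  for an implausibly small predicted field.

## The synthetic cohort generator

Real peak E-field datasets require restricted-access MRI repositories plus
finite-element simulation, so the package ships a generator that emulates
the derived feature/E-field table; every downstream stage is exercised
against it.

* **Features.** 418 participants by default (216 female), age uniform on
  18–87 years, head circumference normal per gender (583 ± 14.5 mm male,
  552 ± 13.5 mm female), cephalic index normal (83.1 ± 4.09), BMI
  log-normal solved to match median 24.05 kg/m² and IQR 20.71–30.56 (only
  the median and IQR are known, and a log-normal is the simplest
  right-skewed family matching them), with 54/418 BMI values missing
  completely at random (only the missing count is known, not a
  mechanism). Feature–feature dependence beyond the per-gender
  circumference means is not modeled — real anatomy is more entangled.
* **Outcomes.** Standardized outcome $z = \beta \cdot x + \varepsilon$
  per montage, back-transformed to V/m around 0.3 V/m with a per-montage
  SD of 0.045 V/m (a ~15% coefficient of variation, the regime reported
  for within-montage peak-field spread) and multiplied by a montage-level
  distance decay $g(d) = c_1/(d + c_2)$ — positive, smooth, decreasing,
  and deliberately neither linear nor quadratic so the two agnostic
  scaling variants remain distinguishable. $g$ is evaluated at the
  montage's template distance: the montage-level dependence of field on
  electrode separation is reproduced while the zero-noise dataset remains
  exactly linear in the five model features (so noiseless runs are an
  exact identifiability check).
* **Ground-truth coefficients.** Negative age, circumference, cephalic
  index, BMI and male-gender effects, with a deterministic ±15%
  per-montage tilt (montage-specific models then genuinely beat averaged
  coefficients). HD-montage coefficients are attenuated (×0.55): HD rings
  induce fields whose variability these accessible predictors explain far
  less of, and the generator reproduces that class difference. The noise
  SD (0.75) places conventional-montage test adjusted $R^2$ in
  [0.35, 0.50].
* **Contamination.** With probability 0.01 the noise is replaced by a
  10-SD deviate, producing roughly 15–20 QC rejections per 4180
  simulations — the attrition scale a curated FEM dataset exhibits.
* **Distances.** Inter-electrode distances scale with head circumference
  via an idealized spherical 10-10 electrode layout and carry a ~5%
  log-normal placement-variability term. Without that term the distance
  would be an exact linear function of circumference within a montage and
  the six-predictor stage-1 designs would be singular; with it, the
  within-montage distance–circumference correlation is realistic and VIFs
  stay moderate.

What passing tests on this generator do **not** show: that real E-fields
are linear in these standardized features, that real placement variability
is log-normal, or that the real HD/conventional performance gap has the
assumed size. The generator establishes that the estimators recover known
truth under the stated structure, that the pipeline is leak-free and
deterministic, and that the dosing arithmetic behaves exactly.

## The evaluation protocol

`run_protocol()` executes the full study design: per-montage 3×IQR QC →
participant 5-fold cross-validation (fold sizes for 418 participants:
84/84/84/83/83) with training-fold-only imputation and standardization →
robust montage-specific fits per montage → agnostic fits per variant with
leave-one-montage-out validation inside each montage class (conventional
and HD separately) → adjusted $R^2$ and NRMSE per fold → dosing comparison
(standardized vs fixed, target 0.1 V/m) with Brown–Forsythe tests,
Bonferroni-corrected across the ten montages. The report is bit-reproducible
given the seed, which with the problem sizes above completes in a few
seconds on one CPU; the test suite runs the protocol at n = 418 across 20
seeds and smaller cohorts (n = 80–150) for structural checks.

In the noiseless limit, montage-specific fits are exact (adjusted
$R^2 = 1$, NRMSE $= 0$, standardized-dose SD $= 0$). The agnostic product
forms cannot be exact on the same dataset — an average over montage-tilted
coefficients times a linear-or-quadratic distance factor cannot reproduce
an arbitrary per-montage linear truth — so their noiseless performance is
high but not 1; exact identifiability of the agnostic forms is instead
verified on data generated from those forms themselves.

## Known limitations

* Electrode coordinates are idealized spherical 10-10 positions, not
  digitized scalp measurements; the packaged CSV is swappable.
* The head-circumference measurement operates on supplied template
  contour points and affine transforms; no image I/O is performed here.
* Montage-agnostic models interpolate over very few distinct montages
  (six conventional, four HD); leave-one-montage-out estimates for HD
  montages are correspondingly unstable, in line with the inconsistent
  HD results the underlying approach reports.
* The dosing comparison assumes strict current–field linearity and makes
  no claim about behavioral or clinical effect sizes.

## A worked example

```{r example}
dataset <- synthetic_dataset(cohort_spec(seed = 1))
report <- suppressWarnings(run_protocol(dataset, run_config(seed = 1)))
report$counts$pairs_retained
round(report$summary$ms_mean_adj_r2, 3)
round(report$summary$sd_reduction_pct, 1)
```

A single participant's dose, from a montage-specific model prediction of
0.25 V/m at 1 mA and a 0.1 V/m target:

```{r dose}
individualized_current(0.25, e_target = 0.1, max_current = 4)
```
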