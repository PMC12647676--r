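# tesdose

Dose standardization for transcranial electrical stimulation (tES)
without participant-specific MRI.

The electric field a fixed tES current induces in the brain varies up to
two-fold between individuals, so a fixed current delivers an inconsistent
dose. `tesdose` predicts each participant's **peak E-field strength** —
the 95th percentile of the E-field magnitude over grey-matter voxels at a
1 mA reference current — from predictors any lab can collect (age, gender,
head circumference, cephalic index, BMI, inter-electrode distance), and
converts the prediction into an individualized current that equalizes the
delivered dose across a population.

It is intended for tES researchers and methodologists who want
individualized dosing, or who want to study how far accessible predictors
can substitute for full MRI + finite-element simulation pipelines.

## What it implements

* **Montage-specific models** (one per electrode layout): robust multiple
  linear regression of the standardized peak E-field on the five
  standardized predictors,

  `E_MS = b1*x_age + b2*x_HC + b3*x_CI + b4*x_BMI + b5*x_gender + b0`,

  fit by iteratively reweighted least squares with Tukey's bisquare weight
  (k = 4.685) and screened with variance inflation factors (< 2.5).
* **Montage-agnostic models** that generalize to unseen montages by
  averaging coefficients across montages and scaling with the
  inter-electrode distance `x_ED`, linearly
  (`E = (S*x_ED) * (inner term incl. x_ED)`) or quadratically
  (`E = (S1*x_ED^2 + S2*x_ED + S3) * (inner term)`), validated
  leave-one-montage-out.
* **Individualized dosing**: `I = I_applied / E_generated * E_target`,
  with a flagged safety cap, plus the fixed-dose comparator and
  Brown–Forsythe/Levene variance comparisons (Bonferroni-corrected).
* **E-field summarization**: 95th-percentile peak over grey matter,
  focality (volume at or above 75% of the 99.9th percentile), per-montage
  3×IQR outlier rejection.
* **Feature extraction**: head circumference from template contour points
  through inverse affine transforms, cephalic index, inter-electrode
  distances on a packaged idealized 10-10 electrode layout, median BMI
  imputation, and all standardization rules.
* **A synthetic cohort generator** reproducing the feature distributions,
  negative feature–field associations, montage-level distance dependence,
  heavy-tailed contamination and BMI missingness of a curated 418-person
  simulation dataset, so the entire pipeline is testable without
  restricted-access imaging data.
* **The full evaluation protocol** (`run_protocol()`): QC, 5-fold
  participant cross-validation, leave-one-montage-out agnostic
  validation, adjusted R², NRMSE, the correlation battery and the dosing
  comparison, bit-reproducible under a fixed seed.

## Worked example

```r
library(tesdose)

dataset <- synthetic_dataset(cohort_spec(seed = 1))   # 418 participants, 10 montages
report  <- run_protocol(dataset, run_config(seed = 1))

report$counts$pairs_retained
#> [1] 4162                      # of 4180 simulated fields; 18 rejected by the 3xIQR rule

round(report$summary$ms_mean_adj_r2, 3)
#> conventional           HD
#>        0.429        0.166     # out-of-fold adjusted R^2, montage-specific models

round(report$summary$sd_reduction_pct, 1)
#> conventional           HD
#>         25.5         11.5     # % SD reduction of realized dose vs fixed dosing
```

Montage-specific models explain ~43% of peak-field variance for
conventional montages (less for high-definition rings, whose fields the
accessible predictors explain less of), and standardized dosing shrinks
the population spread of the realized dose by ~25% for conventional
montages. Dosing a participant whose predicted field is 0.25 V/m at 1 mA,
for a 0.1 V/m target:

```r
individualized_current(0.25, e_target = 0.1, max_current = 4)
#>   current clipped
#> 1     0.4   FALSE              # mA
```

A thin command-line interface wrapping these functions is installed at
`inst/cli/tesdose` (subcommands `simulate-cohort`, `fit-montage`,
`fit-agnostic`, `evaluate`, `dose`).

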