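---
title: "Estimating chronotype and social jetlag from wearable sleep records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chronotype and social jetlag from wearable sleep records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronojet)
```

## The problem

Chronotype — a person's propensity to sleep at a particular time of the
24-hour day — is constrained on work days by social obligations. The
misalignment between sleep timing on free and work days is *social jetlag*
(SJL). Wearable devices record sleep onset and wake times night after
night, which allows both quantities to be estimated objectively instead of
by questionnaire. chronojet implements that estimation pipeline: per-night
mid-sleep points, per-subject aggregates, the sleep-debt-corrected
mid-sleep on free days (MSFsc) as the chronotype statistic, and the
cohort-level statistics built on top of them.

## The night axis

Every nocturnal timestamp is mapped to decimal hours since 12:00 noon of
the evening the night begins (`clock_to_axis()`). A 23:30 onset sits at
11.5, a 07:17 wake at 19.283. Any plausible nocturnal episode lies strictly
inside one noon-to-noon window, so onset < wake always holds on the axis
and plain linear means of axis values are exact — no circular statistics
are needed. Circular means would differ only for schedules so extreme
(mid-sleep near noon) that the exclusion filters remove them; this is a
deliberate simplification, and `mid_sleep()` enforces the window as a
precondition rather than silently wrapping. The same reasoning makes SJL a
plain difference of axis means, signed: negative SJL (earlier mid-sleep on
free days) is a real phenomenon, not an artifact, and is never
absolute-valued.

## Definitions and conventions

- **Mid-sleep** uses the raw onset and wake timestamps. Wake after sleep
  onset (WASO) is subtracted only from *durations* (nocturnal sleep = time
  in bed − WASO); whether device onset/wake timestamps already exclude WASO
  is ambiguous in general, and defining mid-sleep purely from the two
  timestamps is the convention adopted here.
- **Work/free nights**: nights beginning Sunday–Thursday are work nights,
  Friday–Saturday free nights. Weeks are anchored on Sundays so every
  complete week holds exactly 5 work and 2 free nights, which the MSFsc
  formula's 5/7–2/7 weighting presumes.
- **MSFsc** is computed per complete week as
  `MSF − 0.5·[SDf − (5·SDw + 2·SDf)/7]` and averaged over a subject's
  complete weeks (at least 2 by default, configurable via `min_weeks`). The
  correction is applied *unconditionally*, also when `SDf < SDw` (the
  subject accumulated no debt and MSFsc comes out later than MSF). The MCTQ
  questionnaire tradition corrects only when `SDf > SDw`; the unconditional
  form matches the printed formula this pipeline follows, and the choice
  matters only for the minority of subjects who sleep less on free days.
- **Chronotype cut-offs**: early < 3:00, late > 5:00, intermediate in the
  closed interval [3:00, 5:00]. The boundary assignment (3.0 and 5.0 to
  intermediate) follows from reading the early/late inequalities as strict;
  proportions near the cut-offs are sensitive to this, which is why
  `classify_chronotype()` exposes the cut-offs as a parameter.
- **Nap groups**: zero (mean nap exactly 0), long (> 30 min), short
  otherwise; 30.0 falls to short because "long" is strict.
- **Exclusions**: the 3–13 h nocturnal-sleep band is applied to the
  *per-subject mean*, not per night — the rule describes a subject
  property, and per-night removal would silently fragment recording weeks.
  A per-night variant is available (`per_night = TRUE`). Age (10–90) and
  BMI (10–50) bounds are inclusive and only enforced when the value is
  present; a missing age does not remove a subject from SJL analyses but
  does remove them from the chronotype cohort (`require_age_for_msfsc`),
  mirroring the two nested cohorts such studies report. Duplicated
  subject-nights are a hard error: two conflicting records for the same
  night cannot be merged defensibly.

## Statistical analyses

Correlations are Pearson with pairwise deletion (cohort n's differ across
variable pairs when BMI or MSFsc is missing); group comparisons are Welch
t tests (pooled-variance available via `welch = FALSE`); both are two-sided.
SJL regressions are OLS with fixed units — SJL in hours, durations in
minutes — so slopes read directly as hours per minute. The significance
convention for large cohorts (P < .001) is a reporting choice, not baked
into any computation.

`feature_importance()` regresses SJL or MSFsc on sex, age, BMI, mean daily
steps (an exercise indicator), mean nocturnal sleep and mean nap duration,
using only complete cases so missingness cannot distort the weights. The
grid — 10 to 50 trees in steps of 10, maximal depth 2 to 5 — is scored by
mean 5-fold cross-validated R², the best point refit on all data, and
impurity importances normalised to sum to 1. Folds are a seeded random
partition; fits run single-threaded with per-fit seeds, so results are
bit-reproducible. All predictors are considered at every split
(`mtry = p`), the conventional default for regression forests; leaf-size
and subsampling defaults are the ranger library's. When the target is SJL,
MSFsc is not offered as a predictor: it correlates strongly with SJL and
would mask the remaining features. Ties in the grid go to the smaller
forest, then the shallower tree.

## The synthetic-cohort generator

`simulate_cohort()` exists so that every stage — parsing, filtering,
aggregation, statistics — can be validated against known ground truth. Its
defaults encode the population structure the pipeline targets:

- work-night onset 00:15 (SD 70.5 min) and wake 7:00 (SD 66.3 min); free
  nights shifted +13 min (onset) and +22 min (wake), so the implied mean
  SJL is 17.5 min ≈ 0.29 h;
- mean nocturnal durations 387 min (work) and 396 min (free), via a WASO
  mean of 18 min on a 405-min work-night time in bed;
- 94% of subjects napping, nap means gamma-distributed with mode 24 min and
  most naps under 60 min;
- a biphasic age trajectory of chronotype: rising from 3.0 clock hours at
  age 10 to a peak of 4.0 at age 22, declining to 2.8 at 80
  (`msfsc_age_trajectory()`). The start and end values are the package's
  choice of a plausible hinge; only the peak location/height and the
  monotone directions are externally constrained;
- sex mix 64/14/22% male/female/unknown, BMI concentrated 17–30, ages
  concentrated 20–50.

Three structural parameters are *derived* rather than free. First, the
printed onset, wake and duration SDs jointly imply how much onset and wake
co-vary: `Cov(onset, wake) = (SD_on² + SD_wake² − SD_dur²)/2`, giving a
shared latent circadian phase with SD ≈ 59 min; the generator draws one
phase per subject (tied to the age trajectory) plus independent onset/wake
residuals. Second, the per-subject free-night shift SD (0.7 h) is the
excess of the free-night onset SD (82 min) over the work-night onset SD.
Third, the nap–nocturnal coupling — each nap minute above the cohort mean
removes `nap_coupling` minutes of nocturnal sleep, applied symmetrically
around mid-sleep so naps affect durations but never timing — is solved from
`r = λσ_nap / sqrt(σ_dur² + λ²σ_nap²)` at the target correlation −0.22,
giving λ = 0.52.

Night-to-night noise (default SD 30 min on onset and wake) is a free
parameter: cohort studies report only between-subject SDs of means, not
within-subject variability, so 30 min was chosen once as a realistic
device-scale figure. All times are rounded to the minute, like device
output, and ground truth (`true_msfsc_h`, `true_sjl_h`) is computed from
each subject's minute-rounded latent schedule — it is exactly what the
pipeline would recover with zero night-to-night noise, which is what the
noiseless recovery tests assert. Everything flows from one root seed in a
fixed draw order, so identical seed and config give byte-identical CSVs.

What the generator does **not** emulate: shift work and irregular
schedules, seasonal drift, nap timing (only durations), missing nights
inside a week, device staging error, and any causal pathway between
napping and SJL. Passing recovery tests therefore show the *estimator* is
correct under the stated population model, not that the model captures
every feature of real device data.

## Numerical choices and degenerate inputs

Means of clock times are linear on the night axis (exact under the window
assumption). `msfsc_week()` returns MSF *identically* when `SDf = SDw` —
the bracket cancels algebraically, and tests assert machine-precision
equality. Subjects without both work and free nights are flagged
incomplete and excluded from SJL tables rather than erroring; an empty
cohort is an error in `summarize_cohort()` but legal in
`apply_exclusions()`. Histograms use 0.5-h bins anchored at integer hours.
Zero-variance inputs to correlations and degenerate groups in t tests are
errors, not NaNs. CV R² is computed against the held-out fold's own mean,
so pure-noise predictors score at or below zero.

## Problem sizes

The validation suite runs cohorts of 5,000 subjects × 4 weeks for
parameter recovery (rank correlation between latent and estimated
chronotype > 0.99 observed, asserted > 0.9), 20,000 synthetic SJL draws
for the normal-tail check of the report fractions, 500 subjects for
importance recovery under the full 20-point grid, and the full 1-minute
onset×wake grid (≈ 1.03 million pairs) for the mid-sleep oracle. These
sizes give Monte-Carlo error comfortably below every asserted tolerance
while keeping the suite fast.

## Known limitations

- The work/free calendar is fixed (Friday/Saturday free); subjects who
  work weekends are misclassified, which attenuates SJL toward zero.
- Chronotype cut-offs are population-sensitive; the defaults are the
  conventional 3:00/5:00 values and should be revisited for cohorts with
  very different distributions.
- Mid-sleep ignores WASO placement; a long WASO early vs late in the night
  shifts true sleep midpoint but not the estimate.
- The MSFsc correction assumes the 5+2 week structure; cultures with
  different work weeks need a different weighting, which the code does not
  currently parameterise.
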