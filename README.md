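# chronojet

Chronotype and social-jetlag analysis of longitudinal wearable-device sleep
records, for sleep researchers and chronobiologists working with
per-night onset/wake data rather than questionnaires.

## What it computes

For each subject-night the **mid-sleep point** is the clock time halfway
between sleep onset and final awakening (onset 00:00 and wake 08:00 give
4:00 am). All arithmetic happens on a *noon-anchored night axis* — hours
since 12:00 noon of the evening the night begins — so the midnight
wrap-around never enters any calculation and linear averages of times are
exact.

Per subject, over nights classified as **work** (starting Sunday–Thursday)
or **free** (Friday–Saturday):

- **MSW, MSF** — mean mid-sleep on work and free nights;
- **SJL** (social jetlag) — the signed misalignment `SJL = MSF − MSW`;
  negative when free-night mid-sleep is *earlier* than work-night mid-sleep;
- **MSFsc** — mid-sleep on free days corrected for work-week sleep debt,

  `MSFsc = MSF − 0.5 · [SDf − (5·SDw + 2·SDf)/7]`

  with `SDw`/`SDf` the mean nocturnal sleep durations (time in bed minus
  WASO) on work/free nights. MSFsc is computed per complete Sunday-anchored
  week (5 work + 2 free nights) and averaged over a subject's weeks;
- **chronotype** — early (MSFsc < 3:00), intermediate (3:00–5:00), late
  (> 5:00); **nap group** — zero / short (≤ 30 min) / long (> 30 min) mean
  daily nap.

Cohort level: exclusion filters (mean nocturnal sleep 3–13 h, age 10–90,
BMI 10–50, ≥ 7 consecutive nights), SJL/MSFsc distributions and the
negative-SJL breakdown by chronotype, Pearson correlations, Welch t tests,
OLS regressions of SJL on nap and nocturnal durations, and a 5-fold
cross-validated random-forest grid search (10–50 trees, depth 2–5) that
reports unit-sum relative feature importances for sex, age, BMI, steps,
nocturnal sleep and nap duration.

A synthetic-cohort generator (`simulate_cohort()`) emits records with known
per-subject ground truth so every stage is testable end-to-end without
access to proprietary device data.

## Worked example

```r
library(chronojet)

sim <- simulate_cohort(n_subjects = 2000, n_weeks = 4, seed = 42)
res <- analyze_cohort(sim$records, sim$subjects,
                      run_config(seed = 42, importance = FALSE))
res
#> <cohort_analysis>
#>   retained subjects: 2000 of 2000
#> <cohort_report>
#>   subjects: 2000 (SJL n = 2000, chronotyped n = 1893)
#>   SJL: mean 0.33 h (SD 0.72); P(SJL > 1 h) = 17.3%, P(SJL < 0) = 31.9%
#>   chronotypes: early 24.1%, intermediate 56.7%, late 19.2%
```

All 2000 subjects pass the exclusion filters; 1893 have at least two
complete recording weeks *and* a recorded age, so they enter the chronotype
cohort. Mean SJL is 0.33 h — free-night mid-sleep is about 20 minutes later
than work-night mid-sleep on average — yet 31.9% of subjects have negative
SJL (earlier mid-sleep on free days), and only 17.3% exceed one hour of
social jetlag.

Because the cohort is simulated, estimates can be checked against the
generator's ground truth:

```r
recover_truth(res$summaries, sim$truth)
#> # A tibble: 2 × 5
#>   metric     n    bias  rmse rank_cor
#> 1 msfsc   1893 0.00106 0.165    0.990
#> 2 sjl     2000 0.00123 0.157    0.974
```

Four recording weeks recover each subject's latent chronotype with
negligible bias, 10-minute RMSE and rank correlation 0.99.

```r
fit <- feature_importance(res$summaries, target = "msfsc", seed = 42)
tidy(fit)
#> # A tibble: 6 × 2
#>   feature        importance
#> 1 age_years          0.648
#> 2 mean_steps         0.164
#> 3 bmi                0.0893
#> 4 mean_nap_min       0.0706
#> 5 mean_sleep_min     0.0281
#> 6 sex                0
```

Age dominates the prediction of MSFsc (the generator drives chronotype
through a biphasic age trajectory peaking at age 22), while sex carries no
importance — the simulated sex effect acts on sleep *duration*, not timing.

Plots: `plot_sjl_histogram()`, `plot_msfsc_histogram()`,
`plot_age_msfsc()` and `autoplot()` methods on report and forest objects.
`write_cohort_report()` serialises every table as CSV plus a JSON manifest
from which a run is fully reproducible; `inst/scripts/chronojet-cli.R` is a
thin command-line wrapper (`simulate` / `analyze` subcommands).

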