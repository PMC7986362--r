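# dialacc

Wrist-accelerometer physical activity analysis for haemodialysis cohorts.

People on maintenance haemodialysis are candidates for objective activity
monitoring — questionnaires suffer recall bias, and the treatment schedule
itself structures their day — but standard accelerometry pipelines do not
handle a cohort whose week alternates between dialysis and non-dialysis
days. `dialacc` implements the full chain for this setting, for
biostatisticians and nephrology researchers working with wrist-worn
triaxial devices:

- **Preprocessing**: unit-sphere autocalibration from stationary windows,
  resampling, and ENMO vector magnitude,
  `vm = max(0, sqrt(x^2 + y^2 + z^2) - 1 g)`, summarised in mg over 5-s
  epochs.
- **Dialysis-aware wear QC**: non-wear detection (stationary runs >= 60
  min), day-type labelling from the treatment weekday pattern, the
  *excellent wear* inclusion criterion (>= 72 h worn and every clock hour
  covered, separately on dialysis and non-dialysis days), and 1-min
  imputation from same-clock-time donors strictly within day type.
- **Functional behaviours**: balanced random forests (every tree's
  bootstrap down-samples all classes to the rarest class's count) over
  30-s epoch features, smoothed by Viterbi decoding of an HMM whose
  transitions come from labelled sequences and whose emission is the
  forest's out-of-bag confusion. Five states: walking, light tasks,
  moderate-intensity activity, sedentary, sleep.
- **Questionnaires**: KCCQ domain scores, Functional Status Score and
  Clinical Status Score on 0-100; EQ-5D-3L domains and VAS (no tariffs).
- **Cohort statistics**: mean (SE) tables by subgroup and day type, paired
  day-type t-tests, linear-model marginal means adjusted for age, sex and
  leg weakness, Spearman correlations with questionnaire scores,
  time-of-day profile curves, and greedy age/sex/season-matched control
  selection.
- **A calibrated synthetic cohort generator** (epoch and raw tiers) with
  known truth, so the whole pipeline is testable without any participant
  data; its defaults emulate a 73-person thrice-weekly dialysis cohort
  with a ~4-h session dip, early waking before morning slots, an age
  gradient and a leg-weakness deficit.

## Worked example

Generate the default synthetic cohort, run QC -> classification ->
imputation -> summaries, and look at the headline statistics:

```r
library(dialacc)

run <- run_cohort_pipeline(generator_config(), seed = 20201)
print(run$model)
#> <behaviour_model> 100 trees, OOB accuracy 0.992, HMM attached

hs <- cohort_headline_stats(run)
round(unlist(hs[c("vm_overall", "vm_dialysis", "vm_nondialysis",
                  "hours_walking", "hours_sedentary", "hours_sleep")]), 2)
#>     vm_overall    vm_dialysis vm_nondialysis  hours_walking
#>          15.65          14.88          16.30           0.97
#> hours_sedentary    hours_sleep
#>          13.23           8.60
```

The cohort is overall at ~15.6 mg of mean vector magnitude — less active
on dialysis days (14.9 mg) than non-dialysis days (16.3 mg) — and spends
about 1 h/day walking, 13.2 h sedentary and 8.6 h asleep: the pipeline
recovers the generator's calibrated truth. Subgroup contrasts follow the
built-in gradients (means (SE) in mg):

```
age youngest 18.6 (0.66)   oldest 13.4 (0.83)
leg weakness 13.5 (0.51)   without 18.5 (0.64)
```

and the paired dialysis/non-dialysis test on vector magnitude gives a
within-person difference of -1.32 mg (t = -16.5, p < 1e-25). A healthy
population control pool generated and summarised the same way averages
28.1 mg, an activity ratio of 0.56 for the dialysis cohort.

The numbered scripts under `analysis/` run the same study as a file-based
workflow (simulate -> train classifier -> QC/predict/summarise -> cohort
statistics -> matched-control comparison), writing tables under
`results/`.

## Layout

```
R/                      package code (generator, preprocessing, QC,
                        behaviour model, questionnaires, cohort statistics)
src/                    Viterbi decoding (Rcpp)
analysis/01..05*.R      the analysis workflow over the package
scripts/acceptance.R    end-to-end reproduction script
tests/testthat/         unit, property and end-to-end recovery tests
vignettes/              methods vignette: models, assumptions, calibration
```
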