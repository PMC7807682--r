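# actibed

Wrist actigraphy, time in bed, and sedentary behaviour in older adults.

`actibed` reconstructs, as a tested and reusable R pipeline, the analysis
that links objectively measured physical activity and sedentary behaviour to
self-reported time in bed (TIB) in community-dwelling adults aged 75+ who
wear a tri-axial accelerometer on the dominant wrist for 7 days and keep a
wear-time diary. It is aimed at epidemiologists and movement scientists who
work with per-minute count data plus sleep diaries, and at methodologists
who want a fully synthetic, seeded test bed for this class of pipeline.

## What it computes

Starting from per-minute vector-magnitude counts (cpm), diary bed/rise/nap
times and a covariate table, the pipeline:

1. **Detects non-wear**: runs of ≥ 30 min of continuous zero counts,
   allowing one single spike below 100 counts, are non-wear
   (`detect_nonwear()`).
2. **Masks diary TIB** as non-wear, with TIB taking precedence
   (`apply_masks()`).
3. **Summarises wear time** between 05:00–24:00 (maximum 19 h/day), with
   sedentary behaviour (SB) at 0–2302 cpm and higher-intensity bands at
   2303–4999 and ≥ 5000 cpm; band percentages use wear time as the
   denominator (`daily_summary()`). A valid day has ≥ 10 h of wear and a
   participant needs ≥ 4 valid days (`participant_exposure()`). "Highly
   sedentary" means pooled %SB ≥ 65% of wear time.
4. **Categorises TIB**: a night is in range at 7–9 h; participants are
   UTIB (≥ 80% of measurement nights in range), STIB (20–79%) or RTIB
   (< 20%) (`tib_categorize()`).
5. **Models the categories**: baseline-category multinomial logit with UTIB
   as reference. For outcome *k* ∈ {STIB, RTIB} and design row *x*,

   log [ P(Y = k | x) / P(Y = UTIB | x) ] = xᵀβₖ,

   fitted by Newton–Raphson maximum likelihood (gradient tolerance 1e-8);
   exp(βₖ) are relative risk ratios (RRR) with Wald 95% CIs from the
   observed information, likelihood-ratio tests for the exposure block, and
   delta-method CIs for predicted probabilities and probability contrasts
   (`fit_multinom_rrr()`, `fit_tib_model()`, `predicted_probabilities()`,
   `probability_contrast()`). Model I adjusts for age, sex, daily nap
   length and the SPPB physical-function score; Model II (for the
   highly-sedentary exposure) additionally adjusts for % time ≥ 5000 cpm.
6. **Sensitivity analysis**: removing sleep by a fixed 23:00–08:00 window
   instead of the diary misclassifies in-bed time as sedentary wear;
   `compare_sleep_removal()` quantifies the %SB inflation.

Because person-level data of the motivating cohort are not publicly
available, `generate_cohort()` provides a seeded synthetic cohort with the
matching statistical structure (nightly TIB centred at 8 h 21 min, daytime
counts occupying the three bands at 64/23/13%, naps near 40 min/day, shower
non-wear gaps, covariates correlated with activity), and
`generate_from_logit()` draws category labels from a known multinomial
logit for parameter-recovery testing.

## Worked example

```r
library(actibed)

cfg <- pipeline_config(cohort_config(n_participants = 341, seed = 1))
report <- run_pipeline(cfg)

report$flow
#>               stage   n
#> 1           entered 341
#> 2 excluded_validity   0
#> 3          retained 341

table(report$analysis_table$tib_category)
#> UTIB STIB RTIB
#>   98  203   40

m <- fit_tib_model(report$analysis_table, "avg_cpm")
print(m)
#> Study Model I, exposure avg_cpm (n = 341)
#>  outcome                  term   rrr rrr_lower rrr_upper p_value
#>     STIB avg_cpm_tertilemiddle 0.885     0.473     1.660  0.7030
#>     STIB   avg_cpm_tertilehigh 0.858     0.448     1.640  0.6450
#>     RTIB avg_cpm_tertilemiddle 0.288     0.110     0.759  0.0118
#>     RTIB   avg_cpm_tertilehigh 0.352     0.135     0.915  0.0321
#> Overall exposure p (LR test): 0.05906

probability_contrast(m$fit, "avg_cpm_tertile", "high", "low")
#>   category    contrast         se       lower       upper    p_value
#> 1     UTIB  0.06071372 0.05995548 -0.05679685  0.17822429 0.31122889
#> 2     STIB  0.05410725 0.07008764 -0.08326201  0.19147650 0.44011791
#> 3     RTIB -0.11482097 0.05204538 -0.21682804 -0.01281389 0.02737209

print(report$sensitivity)
#> Sedentary %-point inflation, fixed-window vs diary removal: median 0.30 (n = 341)
```

Reading the output: on this synthetic cohort of 341 participants, being in
the highest tertile of average counts per minute cuts the relative risk of
rarely achieving 7–9 h in bed (RTIB vs UTIB) to 0.35 (95% CI 0.14–0.92)
and lowers the probability of being RTIB by 11.5 percentage points (95% CI
1.3–21.7); removing sleep with the fixed 23:00–08:00 window instead of the
diary inflates the sedentary percentage by a median 0.30 points.

A thin command-line wrapper is installed as `exec/actibed` with
`simulate`, `process`, `analyze`, `sensitivity` and `run` subcommands over
the same functions.

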