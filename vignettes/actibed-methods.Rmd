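---
title: "Methods: from wrist counts and bedtime diaries to time-in-bed risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist counts and bedtime diaries to time-in-bed risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actibed)
```

## The analysis in one paragraph

`actibed` processes week-long per-minute wrist accelerometer recordings
(vector-magnitude counts per minute, cpm) together with bedtime diaries
from adults aged 75+. Sustained zero-count runs are treated as non-wear,
diary-reported time in bed (TIB) is masked out, and daily physical
activity and sedentary behaviour are summarised over a 05:00–24:00 window
using wear time as the denominator. Participants are categorised by how
often their nightly TIB falls in the 7–9 h range considered appropriate
for this age group — usually (UTIB, ≥ 80% of nights), sometimes (STIB,
20–79%) or rarely (RTIB, < 20%) — and a baseline-category multinomial
logit with UTIB as reference estimates relative risk ratios (RRR) of
being STIB or RTIB by activity exposures, adjusted for age, sex, daily
nap length and lower-extremity function (SPPB score).

## Epoch and diary conventions

Epochs are half-open minutes `[t, t + 60 s)`; an epoch belongs to a
calendar day and to any diary interval by its **start** time, which avoids
double counting at boundaries. All timestamps are naive local clock times
(stored as UTC internally); daylight-saving transitions are not modelled.
Missing epochs are explicit `NA` counts — a gap in the minute grid is a
format error, so alignment bugs surface at read time rather than as
silent shifts.

A diary day is anchored on the evening it describes. Bed times between
24:00 and 05:00 are attached to the *preceding* night: a row dated `d`
with bed time 00:30 becomes the night of `d − 1` starting at 00:30 on
`d`. The 05:00 boundary follows the summarisation window; in data of this
kind almost all post-midnight bedtimes fall well before 05:00, and rise
times are resolved as the first matching clock time after bed. Naps
recorded in the same row stay with that diary day. Diary naps are **not**
masked as non-wear: only the nightly bed-to-rise interval is, so napping
typically accrues as sedentary wear and nap length enters the models as a
covariate instead.

## Non-wear detection

A non-wear period is a run of at least `min_duration = 30` epochs that are
all zero except for at most `max_spikes = 1` epoch with a count strictly
below `spike_ceiling = 100`; "below 100" is read literally, so a count of
exactly 100 breaks the run, and the spike epoch counts toward the
duration. The spike allowance applies once per detected run, not once per
30-minute window. Runs truncated by the recording edge qualify if long
enough, since wear status beyond the edges is unknowable either way.

Because qualifying windows can overlap (two spikes 30 zeros apart create
overlapping candidates that cannot be merged without exceeding the spike
allowance), detection is defined greedily and deterministically: report
the earliest-starting qualifying run, extended as far right as the spike
allowance permits, then continue after its end. Reported intervals never
overlap. One consequence worth knowing: relaxing the spike ceiling can
*re-segment* runs (a newly eligible spike earlier in a stretch consumes
the allowance sooner), so the detected epoch set is not monotone in the
ceiling, although every detected interval trivially remains a qualifying
window under the relaxed rule. Lowering the minimum duration only adds
detected epochs. The test suite checks the detector against an
independent brute-force enumeration on a thousand random series.

In the main pipeline, detection runs on the raw count series and the mask
then labels epochs TIB > NONWEAR > WEAR, with TIB taking precedence —
mirroring the field practice of writing zeros into the recording during
reported TIB so that it is picked up as non-wear.

## Exposures, validity and tertiles

Only `WEAR` epochs starting within 05:00–24:00 (at most 19 h/day)
contribute. Sedentary behaviour is 0–2302 cpm (a wrist cut-point
validated for older adults); the 2303–4999 and ≥ 5000 cpm bands describe
relatively higher intensities without claiming equivalence to
moderate/vigorous activity. A day is valid with ≥ 600 wear minutes; a
participant is retained with ≥ 4 valid days (the 10-h minimum is assessed
within the summarisation window, the stated summation domain). The
person-level exposure pools epochs across valid days — total counts over
total wear minutes, total band minutes over total wear minutes — rather
than averaging daily percentages; `pooling = "mean_of_days"` offers the
alternative. "Highly sedentary" is pooled %SB ≥ 65% of wear time (the
absolute ≈ 10 h/day equivalent is a cohort-median correspondence, not the
definition).

Cohort tertiles cut at the empirical 1/3 and 2/3 quantiles (base R type-7
linear interpolation); values equal to a cut point go to the lower
tertile, which makes the assignment deterministic and stable under input
permutation. Identical values across the cohort raise a degenerate-tertile
error rather than an arbitrary split.

## Time-in-bed categorisation

Nightly TIB is rise minus bed in minutes; the 7–9 h range is closed on
both ends (420 and 540 min are in range). The printed category bounds
"≥ 80% / 20–79% / < 20%" are implemented as `[80, 100]`, `[20, 80)` and
`[0, 20)` so the three intervals tile 0–100% exactly — an integer 79
would leave gaps for 7-night denominators. The denominator is the number
of nights with a complete diary entry, not a fixed 7; a night with a
missing diary entry drops from the TIB denominator while its day remains
in the exposure computation if the wear criterion is met.

## The multinomial model

`fit_multinom_rrr()` fits the baseline-category logit by exact
Newton–Raphson on the full observed information with step halving,
declaring convergence when the gradient max-norm falls below 1e-8 (at
most 100 iterations). Divergence (any coefficient beyond ±30) or a
singular information matrix raises a perfect-separation error naming the
worst term; an outcome category with zero observations is an immediate
error rather than a silent collapse to fewer categories. Standard errors
come from the inverse observed information; RRR confidence intervals are
Wald intervals on the log scale (`exp(b ± z·SE)`) — profile intervals are
not offered, and this choice is deliberate and documented since the Wald
form is what the applied literature reports. The overall p value for an
exposure is a likelihood-ratio test of the exposure block. No
multiple-testing adjustment is applied to the model tables.

Predicted probabilities fix continuous covariates at cohort means and
categorical ones at modes (observed-value averaging is not implemented;
the representative-row choice is the common applied default), and their
confidence intervals use the delta method; probability contrasts between
exposure levels are differences of those softmax probabilities with
delta-method variances, so contrasts across the three categories sum to
zero exactly. Sex is coded with male as the reference level; tertiles use
the low tertile as reference. Model I adjusts for age, sex, average daily
nap minutes and SPPB total score; Model II adds % wear time ≥ 5000 cpm
and is reserved for the highly-sedentary exposure (the pairing is
enforced).

The test suite cross-checks coefficients, standard errors and
log-likelihoods against `nnet::multinom` to numerical precision, verifies
the binary collapse against `glm(family = binomial)`, and calibrates the
machinery by simulation: over 200 known-logit cohorts of n = 2000,
refitted coefficients fall within 3 SE of truth in ≥ 95% of replicates,
and over 500 cohorts of n = 341 the pooled 95% Wald coverage of the two
exposure slopes lies between 93% and 97%.

## Sensitivity analysis: fixed-window vs diary sleep removal

`compare_sleep_removal()` runs the summarisation twice — once masking the
diary nights, once masking a fixed 23:00–08:00 window with no diary — and
reports the %SB difference (fixed − diary) per participant and as a
cohort median. Two design points matter:

* **Each arm excises its sleep mask first, and non-wear detection runs
  segment-wise within the unmasked stretches** (a mask boundary breaks a
  zero run). With whole-series detection, an in-bed zero overhang outside
  the fixed window would itself be detected as a ≥ 30-min zero run in both
  arms and the comparison would be identically zero; segment-wise
  detection lets overhangs shorter than 30 min surface as sedentary wear
  under fixed removal, which is precisely the misclassification the
  comparison is designed to expose. The main pipeline keeps whole-series
  detection.
* The summarisation window still applies, so the operative fixed
  exclusion is 05:00–08:00 plus 23:00–24:00, and the day-validity filter
  is *not* applied inside the comparison — otherwise the two arms would
  pool different days for reasons unrelated to the removal method.

The cohort summary is the median (mean available as an option); the
magnitude of the inflation on synthetic data depends directly on how
much in-bed time falls outside the fixed window and on in-bed counts
being zero, so it is a directional check, not a reproduction of any
published cohort value.

## What the synthetic cohort does and does not emulate

`generate_cohort()` draws, per participant, a latent activity trait that
shifts a three-regime count mixture (low / 2303–4999 / ≥ 5000 cpm, default
weights 0.64 / 0.23 / 0.13 — matching published band occupancy), nightly
TIB centred at 501 min (8 h 21 min) with between-person SD 52 min and
night-to-night jitter 45 min (splitting a published overall IQR near
70 min into spread and irregularity), bedtimes around 22:45 with
between-person and nightly jitter (so a minority of bedtimes falls after
midnight), about 40 min/day of naps placed in the 12:00–16:00 window
(published data give daily nap length, not timing), shower non-wear gaps
of 32–75 min at about 0.5/day, and covariates: age 75+, ~62% women, and
an SPPB score generated as a monotone noisy function of the activity
trait clipped to 0–12. The trait correlates negatively with nightly TIB
(−0.35), so sedentariness, long nights and low function co-occur. Counts
during TIB default to exactly zero (`inbed_counts_zero = TRUE`), which
makes the sensitivity-analysis fixtures exact; low-level restlessness can
be switched on instead. All draws run under a private seeded RNG stream,
so identical configuration and seed reproduce the cohort bit for bit.

None of these distributional forms are claims about any real cohort —
the motivating study reports no distributions, only medians and IQRs —
and real data differ in ways that matter: counts are autocorrelated
within bouts rather than independent across minutes, in-bed counts are
not exactly zero, diaries are rounded and occasionally wrong, device
non-wear is not confined to showers, and missingness is not limited to
the validity rule. Passing tests on this generator therefore demonstrate
the correctness and calibration of the *pipeline machinery*, not that any
particular epidemiological estimate transfers to field data.

`generate_from_logit()` sidesteps the epoch level entirely: it draws
category labels from a user-specified baseline-category logit over iid
standard-normal design columns, which is the right tool for
parameter-recovery and coverage simulations.

## Problem sizes and numerical choices

The packaged simulations use cohorts of 341 (the study size) for the
pipeline and coverage runs, 2000 × 200 replicates for parameter recovery,
20 000 draws for logit-fidelity checks, and 1000 random series up to 2000
epochs for the non-wear oracle; the full suite completes in well under a
minute on a single core. Tolerances: gradient max-norm 1e-8 for the
Newton fit; probability sums are exact to 1e-9; band percentages sum to
100 up to floating-point error. Ties: tertile ties go to the lower
tertile; modal covariate ties resolve to the earlier factor level;
`categorize` boundaries are inclusive at 80% (UTIB) and 20% (STIB).
Degenerate inputs fail loudly: zero-wear days are flagged rather than
treated as zero-activity days, all-identical tertile inputs error, and an
empty cohort aborts before any output is written.

## Known limitations

* TIB comes from diaries; no sleep detection from counts is attempted (in
  this population, data-driven wear/sleep inference is itself biased),
  and sleep efficiency within TIB is unavailable by design.
* Raw acceleration → counts conversion is upstream and out of scope; the
  pipeline starts at 60-s epoch counts (`read_device_export()` documents
  the expected CSV instead of parsing vendor binaries).
* The wrist cut-points describe relative intensity only; they are not
  moderate/vigorous equivalents, and hip/thigh placements need different
  cut-points.
* Wald intervals can undercover near separation at small n; the fitter
  errors on separation rather than reporting unstable estimates, and the
  end-to-end pipeline records such model failures per exposure instead of
  aborting the whole report.
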