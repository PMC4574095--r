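---
title: "Methods: accelerometer reduction, comparative analysis and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer reduction, comparative analysis and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcohort)
```

accelcohort implements the data-reduction and analysis conventions used by
pooled youth accelerometry studies, in which ActiGraph count streams from
many cohorts are harmonised with a single rule set before demographic
contrasts (sex, age, weight status, country) are estimated. This vignette
is the package's own account of the methods: the rules, the tunable
parameters, the generative model behind the synthetic cohort, and the
choices made where the conventions leave room.

## 1. Epoch handling

Counts are modelled as a single (vertical-axis) stream at a fixed epoch
length. Files recorded at finer epochs (5--30 s) are reintegrated to 60 s
by summing blocks of consecutive epochs (`reintegrate()`). Three
conventions apply:

* blocks are anchored at the series start, not at clock-minute boundaries;
  if the start is not on a whole minute it is reported rounded down to the
  containing minute, with a warning (recording software differs here and
  the originals rarely document their choice -- this rule is deterministic
  and keeps counts aligned with the device's own integration windows);
* a trailing partial block is dropped rather than zero-padded, because a
  padded block would masquerade as measured wear time;
* count totals are conserved exactly: the sum of output epochs plus the
  dropped tail equals the input sum (property-tested).

Input is a plain CSV dialect (`timestamp,counts`, ISO-8601 local clock
times) or a headerless count column with a JSON sidecar carrying the start
time and epoch length. Gaps are a hard error naming the first offending
row: silently filling a gap would be indistinguishable from device
non-wear downstream.

## 2. Non-wear, wear window, valid days

Non-wear (`detect_nonwear()`) is a maximal run of **>= 60 zero-count
minutes**, inside which non-zero interruption runs of **<= 2 consecutive
minutes** are tolerated; a non-zero run of 3 or more minutes terminates
the interval, and intervals can neither begin nor end on a tolerated
minute. Three details are deliberate:

* the tolerance is on run *length* only -- there is no ceiling on the
  interruption's counts by default. A stricter variant with a count
  ceiling (interruptions must stay below, say, 100 counts) is available
  via `interruption_max_count`, default off;
* the number of tolerated interruption runs per interval is unlimited;
  only each run's length is constrained;
* detection runs over the **whole recording**, and the intervals are then
  intersected with each day's window, so a bout spanning midnight is not
  fragmented into sub-threshold pieces.

Each calendar day is summarised over the **07:00--22:59** window (960
minutes). Wear minutes are recorded window minutes outside all non-wear
intervals; counts-per-minute (cpm) is total counts over wear minutes
divided by wear minutes -- the denominator is *worn* time, not the fixed
960. A day is **valid** with >= 500 wear minutes; a participant-timepoint
enters analysis with >= 3 valid days. One consequence of whole-recording
detection worth knowing: a zero run that crosses the 07:00 boundary
couples pre-window counts to window wear, so "counts outside the window
never matter" holds for perturbations away from boundary-crossing zero
runs, and the property is tested in that regime.

Minute intensity uses the Evenson youth cut-points: sedentary <= 100 cpm,
light 101--2295, MVPA >= 2296 (`pa_cutpoints()` makes these tunable).
Participant-timepoint metrics are **means of daily values over valid
days** -- mean of daily cpm, mean of daily intensity percentages -- not
pooled counts over pooled minutes; with unequal wear time the two
disagree, and the daily-means convention weights days equally. Guideline
adherence is reported both ways used in the field: the **strict** flag
(>= 60 MVPA minutes on *every* valid day) and the **liberal** percentage
of valid days reaching 60 minutes. Strict prevalence can never exceed the
liberal mean percentage; this ordering is property-tested on simulated
cohorts. No bout criteria or weekend-day requirements are imposed.

## 3. Anthropometry

BMI is weight/height^2. Weight status uses the IOTF convention: age- and
sex-specific cut-offs anchored at adult BMI 25 (overweight) and 30
(obese) at age 18, in half-year rows from age 2, linearly interpolated
between rows; ages above 18 (supported to 19) use the adult row. The
bundled table (`inst/extdata/iotf_cutoffs.csv`) is this package's
transcription of the published convention and is versioned with the
package so classification is reproducible offline; swap in your own CSV
via `iotf_cutoffs(path)` to use a different reference. Categories are
mutually exclusive (overweight excludes obese); classification is
monotone in BMI at fixed age and sex (tested), while the cut-off curves
themselves are U-shaped in age, as expected for this reference.

Continuous weight status is BMI standardised within sex by 1-year age
band (`standardize_bmi()`), bands formed as `floor(age)`. Standardisation
here -- and in `standardize_within_country()` -- uses the **population
(divide-by-n) SD**, so a two-member cell maps exactly to (-1, +1); cells
with fewer than 2 members or zero spread cannot be standardised and yield
0 with a warning rather than NaN.

## 4. Statistical layer

Season is a half-year dichotomy: May--October is the summer half in the
northern hemisphere, inverted in the southern (`assign_season()`).

`fit_adjusted_model()` fits OLS with study and season always included as
adjustment factors (a factor that does not vary in the sample is dropped,
since a constant regressor is inestimable). Repeated waves of the same
child are treated as extra cross-sectional records, and inference uses
cluster-robust sandwich standard errors with all waves of a participant
as one cluster. The small-sample convention is CR1 with the factor
G/(G-1) x (n-1)/(n-k) -- the default behaviour of the major commercial
packages -- implemented via `sandwich::vcovCL(type = "HC1")`; with
singleton clusters it reduces exactly to classical HC1, which is tested,
and the full formula is cross-checked against a longhand matrix oracle.
Model structures: additive (`main`), the full age-band-by-sex cross
expressed relative to a reference cell (boys aged 5--6 by default), the
three-way cross with a binary normal vs overweight/obese indicator, and
an additive dose-response form with the 3-level category. Age bands
follow the 2-year descriptive grouping (2--4 merged, then 5--6 ... 17--18).
Confidence intervals are estimate +/- 1.96 SE throughout.

For between-country comparison of *relative* effects, the outcome is
first z-scored within each country (population SD), removing
between-country level differences; per-country regressions are then
pooled by **DerSimonian--Laird random-effects meta-analysis**
(`meta_analyze()`): moment estimator for the between-country variance
tau^2, I^2 = max(0, 100 (Q - (k-1))/Q), heterogeneity p-value from
chi-square with k-1 df. DL is authored in the package (it is part of the
method under study) and cross-checked in tests against both the written-
out formulas and `metafor::rma(method = "DL")`. When tau^2 truncates at
zero the pooling reduces to fixed-effect inverse-variance weighting
(tested). REML or Paule--Mandel tau^2 estimators are deliberately out of
scope.

Two conventions for the age trend deserve a note. `annual_pct_change()`
expresses a fitted per-year cpm difference as a percentage of the
model-predicted level at a *reference age*; the same absolute decrement
is a larger percentage against an older (lower-activity) reference, so
both the age-5 and age-12 anchors are supported and the reference is
always stated. `longitudinal_age_slope()` restricts to participants with
>= 2 waves spanning >= 1 year and to countries whose retained data span
>= 4 years of age, fitting the standardised outcome on continuous age
(adjusted for sex and, where it varies, season) with clustered errors.

## 5. The synthetic cohort generator

No pooled multi-country youth accelerometer dataset is publicly
deposited, so the package ships a generator (`sim_config()`,
`simulate_cohort()`) whose *defaults are the study conditions the
analysis layer is meant to detect*, with every injected effect recorded
in a truth manifest:

* baseline 738 cpm at age 5 and an annual decline of 4.2% of that level
  (31 cpm/yr) after age 5 -- jointly consistent with a roughly 6%/yr
  decline when re-anchored at age 12;
* a boys-minus-girls gap of 0.45 SD (the headline mid-childhood
  contrast; recovery experiments at ages 12--13 set 0.66);
* six countries with additive offsets spanning 110 cpm, i.e. a 15--20%
  spread in total activity at mid-childhood levels;
* weight-status deficits (30/70 cpm for overweight/obese, scaled 1.3x in
  boys, 0.7x in girls) applied from age 7, with category prevalences
  75/18/7%;
* a 30 cpm summer-winter shift; 3--7 measured days per wave (mean 5, the
  field's typical compliance); 25% of participants re-measured two years
  later with the participant random effect carried across waves, so the
  clustering the sandwich estimator corrects for is really present;
* between-participant SD 180 cpm and day-level SD 150 cpm.

Minute counts come from a first-order Markov chain over the three
intensity states with per-state count draws (sedentary 1--100, light
101--2295, MVPA >= 2296), modulated by a double-peaked diurnal profile,
overnight (23:00--07:00) zeros, and injected non-wear bouts: zero runs of
60--120 minutes placed clear of window edges, 30% of long bouts
containing a tolerated 1--2 minute non-zero interruption. Each day's
worn-window counts are then rescaled so realised cpm equals the day
target up to integer rounding. This calibration is what makes the
recovery experiments sharp: the within-sex SD of the measured outcome is
known in closed form, sigma_w^2 = sigma_b^2 + sigma_d^2 E[1/days].

Because the reported sex gap is in SD units of the *pooled* outcome
(which the gap itself inflates), the generator converts the configured
`sex_gap_sd` = g to a cpm gap as g sigma_w / sqrt(1 - g^2/4); the
recovered standardised coefficient then has expectation exactly g. Two
idealisations matter for interpreting test results on real data: worn
minutes always register >= 1 count (true zeros during wear do occur in
real recordings and make non-wear detection genuinely ambiguous there),
and day targets are hit essentially exactly (real day-level cpm has
residual measurement noise). Passing recovery tests therefore show the
*pipeline arithmetic and inference* are right, not that the non-wear rule
is unconfounded on real data. Reproducibility is by a single global seed;
cohorts regenerate byte-identically (tested), with one stream rather than
per-participant substreams since generation is single-threaded.

## 6. Recovery experiments and problem sizes

`recover_sex_gap()` and `recover_age_decline()` run the full chain
(simulate -> reduce -> records -> standardise -> clustered regression) on
cohorts with a single injected effect and report the mean recovered value
with a t-based Monte-Carlo 95% interval across replicates. The package's
standard experiment sizes are 2,000 participants per replicate with 5--10
replicates (the acceptance script uses 10/10/6 for the two sex-gap ages
and the decline); at these sizes a single replicate's sampling SD is
about 0.045 SD for the sex gap and about 0.25 %/yr for the decline, so
the averaged estimates resolve the injected truths to a few percent. The
test suite exercises the same experiments at 5--6 replicates.

## 7. Degenerate inputs and numerical choices

* Empty day tables, all-invalid timepoints and unreachable valid-day
  thresholds produce explicit exclusion rows / clean empty reports, not
  errors.
* Singular regression designs error listing the aliased terms; a single
  cluster errors rather than returning meaningless robust SEs.
* Zero-SD standardisation cells yield z = 0 with a warning.
* cpm is NA (not 0) on days with zero wear.
* Classification boundaries are inclusive on the upper bound of each
  band (100 is sedentary, 2295 is light, 2296 is MVPA); a BMI exactly on
  a cut-off classifies into the higher category.
* All timestamps are handled in a fixed timezone (UTC) as local clock
  time; daylight-saving transitions are out of scope.

## 8. Known limitations

Single-axis counts only (no vector magnitude or raw-acceleration input);
no bout-based MVPA or sleep detection; no imputation of non-wear; the
IOTF table is a bundled transcription, not a live reference; the
generator's Markov chain is test scaffolding, not a biomechanical model
of child movement. The analysis layer assumes complete covariates --
records with missing demographics should be filtered before
`build_analysis_records()`.
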