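---
title: "Detecting and analysing sudden gains in weekly outcome trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing sudden gains in weekly outcome trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suddenstep)
library(dplyr)
```

## The phenomenon and the model

Weekly self-report trajectories in psychotherapy rarely decline smoothly.
A substantial minority of patients show a *sudden gain*: a single
between-week drop that is large in absolute terms, large relative to the
patient's current severity, and large relative to the local week-to-week
fluctuation. `suddenstep` operationalises this on the weekly Liebowitz
Social Anxiety Scale (LSAS, 0–144) with the three-criterion definition:

1. `LSAS(n) − LSAS(n+1) ≥ 12` points. The 12-point cutoff is a
   reliable-change threshold for the LSAS; we treat the boundary as
   inclusive (a drop of exactly 12 qualifies). The wording "a cut-off of
   12" is ambiguous on this point; we chose inclusivity for consistency
   with criterion 2's explicit "at least".
2. The drop is at least 25% of the pre-gain score (inclusive).
3. `mean(pre) − mean(post) > t_crit × s_pooled` over the windows
   `n−2…n` and `n+1…n+3`, with `s_pooled = sqrt((s_pre² + s_post²)/2)`
   (sample SDs) and a *strict* inequality.

"Consecutive" means adjacent week indices with both values observed; an
interval spanning a missing week is never a candidate. Week 1 can never be
a pre-gain week (its pre window has only one slot), which is why pre-gain
histograms start at week 2.

### Missing data and the adjusted critical value

No values are imputed anywhere: imputation can manufacture or destroy
gains. Instead, windows tolerate at most one missing value each
(`min_window = 2`), and the criterion-3 critical value is derived as the
two-sided 95% Student-t quantile with `n_pre + n_post − 2` degrees of
freedom:

```{r}
critical_value(3, 3)  # full windows, the familiar 2.78
critical_value(2, 3)
critical_value(2, 2)
```

This reproduces the canonical 2.776 ("2.78") for full 3+3 windows and is
monotonically more stringent as observations are removed, which is the
property the adjustment must have. The published tables this adjustment
descends from are not reprinted anywhere we could verify against, so the
t-quantile derivation is this package's own, documented choice.

### Reversals, primary gains, summaries

A gain reverses when any later observed score reaches
`score(n+1) + 0.5 × magnitude`, inclusive: for the worked 60→40 example the
threshold is 50. Each participant's *primary* gain — largest magnitude,
ties to the earliest week — enters group analyses; cohort summaries
(occurrence rate, gains per participant, magnitude moments, pre-gain-week
histogram) count *all* qualifying gains, including overlapping intervals.
The occurrence percentage rounds half away from zero. A Mann–Whitney U
test compares treatment duration between gainers and non-gainers, since a
"dose–response" artefact would show up there.

## The mixed models

Both model families use maximum likelihood and a participant random
intercept, fitted with `nlme` and summarised through `emmeans`.

**Outcome model.** `lsas ~ time × sg + baseline_lsas + (1 | id)` over
post-intervention and 3-month follow-up. The interaction makes the
group contrast estimable per timepoint; the reported difference is
no-gain minus gain, covariate-adjusted at the mean baseline.

**Process models.** `value ~ timepoint + (1 | id)` with timepoint the
six-level categorical factor `n−2 … n+3` aligned to each gainer's primary
gain by absolute week arithmetic (offsets off the trajectory edge stay
missing). The five consecutive contrasts are estimated as later minus
earlier marginal means, so improvement is negative.

Numerical and inferential choices worth knowing:

* **Degrees of freedom** for contrast t-tests use `emmeans`' containment
  method on `lme` fits — a between-within approximation, documented as
  such; with 57 gainers and six timepoints it is not a practical
  constraint.
* **Bonferroni family**: correction is applied within each measure across
  its five consecutive contrasts (`p_adj = min(1, 5p)`). The plausible
  alternative (one family across all measures, factor 30) is stricter;
  per-measure families match how such contrast tables are organised and
  read.
* **Cohen's d** is the absolute contrast estimate divided by the pooled
  raw-score SD of the two compared cells,
  `sqrt(((n1−1)s1² + (n2−1)s2²)/(n1+n2−2))`. A model-based standardiser
  (residual SD) was the open alternative; the raw-score version is closer
  to how between-group d values are read clinically, but it mixes
  between-participant variance into the denominator, so d values are not
  comparable across standardisers and published d values computed an
  unknown way should not be expected to match exactly.
* **Degenerate inputs**: on noiseless data the variance estimate sits on
  the boundary and the optimizer reports non-progress although the fixed
  effects are exact; fits therefore use `lmeControl(returnObject = TRUE)`.
  Constant measures yield zero contrasts; zero-dispersion cells make d
  undefined (`NA`, with a message). Measures with fewer than two usable
  timepoints error, naming the measure.

## The synthetic cohort generator

No patient-level data ship with the package; everything is exercised on a
generator whose defaults encode the study conditions the analysis targets:

* durations `round(N(14.53, 3.33))` clamped to 8–30 weeks;
* baseline LSAS `N(85.74, 21.35)` for gainers, `N(80.12, 18.88)` for
  non-gainers (clamped to 35–140 so trajectories stay clinically
  plausible);
* a gradual improvement slope of about 2.2 points/week (consistent with
  non-gainers ending near 49 from a baseline near 80 over ~14 weeks),
  plus AR(1) noise (coefficient 0.3, innovation SD 3 — enough to make
  criterion 3 non-trivial without drowning a 25-point step);
* gains injected as *persistent level shifts* whose magnitudes are drawn
  from a normal truncated to 13–60 points with the latent mean solved so
  the truncated mean equals 25.29 (SD parameter 11.27); pre-gain weeks
  sampled from configurable weights peaking at weeks 2 and 6 (the
  histogram heights behind that bimodality are not published, so the
  weights are configuration, not constants);
* participant-level prevalence 0.39, second gains for 13/57 of gainers;
* completely-at-random missingness (rate 0.10) that spares week 1 and the
  gain interval; the missingness mechanism of real cohorts is unknown, so
  MCAR is an explicit simplification;
* process coupling: cognition frequency drops 5.5 points at week `n` and a
  further 8.2 at `n+1` (standardised ≈ 0.70 and 1.05 given the configured
  between/within SDs — chosen once to match the reported effect-size
  pattern and then frozen), belief and both attention items drop only at
  `n+1`, and PHQ-9 only drifts;
* reversals are opt-in (`reversal_rate`, default 0): a one-week rebound to
  80% of the lost ground, pinned to the post-gain level so it clears the
  50% threshold.

### Certification: the generator knows its own truth

Every simulated trajectory is checked by `oracle_detect()` — a deliberately
plain, independent re-implementation of the three criteria — and redrawn
until the qualifying intervals are *exactly* the injected ones (none, for
non-gainers) and enough LSAS values are observed to pass the 8-datapoint
inclusion filter. Crucially, the structural draw (baseline, gain weeks,
magnitudes) is held fixed while only noise and missingness are resampled,
so certification does not select against small magnitudes and the injected
magnitude distribution stays calibrated. This is what makes sensitivity
and false-positive statements exact: a certified cohort's ground truth is
not "what we intended" but "what an independent checker verified".

`make_replication_fixture()` uses this machinery to build a deterministic
146-participant cohort with exactly 44 one-gain, 13 two-gain and 89
gain-free participants (57 gainers, 39%, 70 gains). Because the structure
is certified, those counts hold for any seed; the documented default seed
(146001) additionally makes the cohort byte-identical across runs.

### What passing tests do and do not show

The generator emulates step-plus-drift trajectories with stationary AR(1)
noise and MCAR missingness. Real trajectories have non-Gaussian scores on
a bounded ordinal scale, informative missingness, therapist and calendar
effects, and gains that need not be clean persistent steps. Passing the
suite therefore shows the *pipeline* is correct (detection matches the
stated criteria exactly; models recover what was injected at realistic n),
not that any clinical effect generalises.

## Problem sizes and verification

The test suite verifies, among other properties: detector–oracle agreement
on 10,000 randomized short trajectories (length ≤ 12, coarse score grid,
up to 2 missing values); 100% sensitivity and zero false positives on a
1,000-participant certified cohort; outcome-model recovery of an injected
25-point group difference (n = 146, residual SD 15) with ~95% CI coverage
and 3–7% type-I error over 500 replicates each; and >80% Bonferroni-power
on the two injected cognition-frequency contrasts (n = 57, 200 replicates)
with <10% on the three null contrasts. These sizes were chosen as the
smallest at which the Monte-Carlo error is comfortably below the margins
being asserted.

## Known limitations

* Detection treats weeks as the session index; calendar time, booster
  sessions, and unequal spacing are out of scope.
* The around-gain models include participants whose gain sits near the
  trajectory end (their `n+2`/`n+3` rows are simply missing); whether such
  participants should be excluded instead is a defensible alternative.
* Sudden *losses*, gradual-gains matching, and mediation/causal analysis
  of the process–symptom ordering are deliberately not implemented.
* All qualifying intervals are counted as gains, including overlapping
  ones; definitions that merge overlapping windows would count fewer.
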