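# suddenstep

Sudden gains are large symptom improvements between two consecutive therapy
weeks. They occur in roughly a third of patients across psychological
treatments, predict better outcomes, and give a window onto mechanisms of
change: if a process variable (negative cognitions, self-focused attention,
mood) moves *before* the symptom drop, it is a candidate driver of it.

`suddenstep` is an R package for running this analysis end to end on weekly
patient-reported outcome trajectories — here, the Liebowitz Social Anxiety
Scale (LSAS, 0–144) collected weekly during internet-delivered cognitive
therapy for social anxiety disorder, alongside the Social Cognitions
Questionnaire (frequency 22–110, belief 0–2200), two self-focused-attention
items (0–8), and the PHQ-9 (0–27).

## The method

A drop from week *n* (pre-gain) to week *n+1* (post-gain) is a **sudden
gain** when all three of the classic criteria hold:

1. **Absolute magnitude** — `LSAS(n) − LSAS(n+1) ≥ 12` points (a
   reliable-change threshold for the LSAS);
2. **Relative magnitude** — the drop is at least 25% of `LSAS(n)`;
3. **Stability** — `mean(pre) − mean(post) > t_crit × s_pooled`, where the
   pre/post windows are weeks `n−2…n` and `n+1…n+3`,
   `s_pooled = sqrt((s_pre² + s_post²)/2)`, and `t_crit` is the two-sided
   95% Student-t quantile with `n_pre + n_post − 2` degrees of freedom:
   2.776 (≈2.78) for full 3+3 windows, rising to 3.182 and 4.303 when a
   window value is missing — missing data make the test *more* stringent,
   never looser. No imputation is performed anywhere.

A gain **reverses** if any later score reaches
`LSAS(n+1) + 0.5 × magnitude` (inclusive: a 60→40 gain reverses at 50). Per
participant, the largest-magnitude gain (ties → earliest) is the **primary
gain** used in group analyses. Around it, the package fits
maximum-likelihood linear mixed models:

* **Outcome model** — `LSAS ~ time × gain-status + baseline + (1 | id)` at
  post-intervention and 3-month follow-up, with covariate-adjusted group
  differences per timepoint;
* **Process models** — `value ~ timepoint + (1 | id)` over the six
  timepoints `n−2 … n+3`, with the five consecutive contrasts,
  Bonferroni-adjusted p-values (`min(1, 5p)`), and Cohen's *d* (contrast
  estimate over the pooled raw SD of the two cells).

A calibrated synthetic-cohort generator injects gains as persistent level
shifts into AR(1)-noisy declining trajectories and *certifies* every
trajectory with an independent brute-force oracle, so detector sensitivity
and specificity are measurable against known ground truth.

## Worked example

```r
library(suddenstep)

# a single trajectory with the classic stable-flanked 60 -> 40 drop
x <- c(82, 75, 71, 60, 60, 60, 40, 40, 40, 38, 36, 35)
detect_gains(x)
#>       n score_n score_n1 magnitude reversed reversal_week
#> 1     6      60       40        20 FALSE               NA
```

One gain: the 20-point drop after week 6 clears the 12-point cutoff, is 33%
of the pre-gain score, and dwarfs the (zero) local fluctuation; it is never
half-lost later, so it does not reverse.

```r
fx <- make_replication_fixture()        # 146 certified synthetic participants
gains <- detect_sudden_gains(fx$cohort)
summarize_gains(gains, fx$cohort)
#> Sudden-gain cohort summary
#>   participants:        146
#>   with >= 1 gain:      57 (39%)
#>   total gains:         70
#>   magnitude mean (SD): 27.77 (7.43)
#>   reversals:           0
```

57 of 146 participants (39%) show at least one gain, 70 gains in total —
exactly the structure the fixture was built to carry (44 participants with
one gain, 13 with two). Process contrasts around the primary gains recover
the injected coupling — cognition frequency starts falling one interval
before the gain:

```r
around <- extract_around_gain(fx$cohort, dplyr::filter(gains, is_primary))
consecutive_contrasts(fit_process_model(around, "scq_freq"))
#>   measure  contrast   estimate    se     p_adj     d
#> 1 scq_freq n-2 vs n-1   -2.16  1.13   2.91e-1  0.28
#> 2 scq_freq n-1 vs n     -6.14  1.02   3.17e-8  0.80
#> 3 scq_freq n vs n+1     -8.91  0.99   5.49e-16 1.25
#> 4 scq_freq n+1 vs n+2   -1.21  0.97   1.00     0.17
#> 5 scq_freq n+2 vs n+3    0.86  1.02   1.00     0.11
```

Only the two injected intervals (`n-1 vs n`, `n vs n+1`) survive the
Bonferroni correction. The outcome model on the same fixture gives gainers
a ~28-point adjusted advantage at post-intervention (*d* ≈ 1.3).

`run_pipeline("report_dir", seed = 1)` runs the whole chain and writes
`gains.csv`, `summary.json`, `outcome_model.csv`, `contrasts.csv`, and the
four standard figures; `inst/scripts/run_pipeline.R` wraps it for the
shell.

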