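# nabiassim

How much spurious correlation between self-reported work stress and
self-reported mental health can negative affectivity (NA) produce on its
own?  `nabiassim` answers that question by Monte-Carlo simulation for the
Siegrist effort–reward imbalance (ERI) questionnaire and the 12-item
General Health Questionnaire (GHQ-12), for researchers in occupational
epidemiology and psychometrics who need to judge whether an observed
ERI–GHQ association could be a common-method artefact.

## The method

1. **Null populations.**  Each of the 29 item responses (6 effort + 11
   reward items rated 1–5, 12 GHQ items scored 0–3) is drawn independently
   from its item-level marginal distribution, for populations of n = 300
   subjects.  Independent items mean *no* true exposure–outcome
   association: the null.  Marginals are estimated from a response matrix
   when one is available, or calibrated from published scale baselines
   (effort 12.5 (1.9), reward 48.1 (3.2), log GHQ 2.29 (0.20)) by
   moment-matched discretized truncated normals.
2. **Bias injection.**  With probability *p* a subject displays NA; each of
   an NA subject's items is affected with probability *q*; an affected
   response moves one level in the "negative" direction (effort and GHQ up,
   reward down), saturating at the scale boundary.
3. **Inference.**  Per population, three OLS regressions of
   log GHQ on: log(ERI ratio); the ratio `E/(R * 6/11)` itself; and effort
   and reward jointly.  Stored: unadjusted R² and strict `p < 0.05`
   significance per coefficient.  Under the null, `E[R²] = k/(n-1)` and
   each coefficient is significant 5% of the time — the calibration
   anchors.
4. **The grid.**  Means of R² and proportions of significant coefficients
   over 10,000 populations per `(p, q)` cell, for
   p ∈ {0, 5, 10, 20}% × q ∈ {0, 10, 20, 30, 40}%, with shared random
   numbers across cells.  An observed explained variance is then read
   against the surface: ≤ 5% — interpret with caution; 5–10% — possibly
   NA, though unlikely; ≥ 10% — not likely NA.

## Worked example

```r
library(nabiassim)
cfg <- run_config(n_populations = 500, p_grid = c(0, 0.10, 0.20),
                  q_grid = c(0, 0.20, 0.40), master_seed = 42)
grid <- run_grid(cfg)
grid[order(grid$p_subject, grid$q_items),
     c("p_subject", "q_items", "log_ratio_mean_r2_pct",
       "log_ratio_prop_sig", "mean_eri_ratio", "mean_log_ghq")]
```

```
 p_subject q_items log_ratio_mean_r2_pct log_ratio_prop_sig mean_eri_ratio mean_log_ghq
       0.0     0.0                 0.372              0.066          0.479         2.29
       0.0     0.2                 0.372              0.066          0.479         2.29
       0.0     0.4                 0.372              0.066          0.479         2.29
       0.1     0.0                 0.372              0.066          0.479         2.29
       0.1     0.2                 0.854              0.240          0.486         2.31
       0.1     0.4                 4.909              0.948          0.494         2.33
       0.2     0.0                 0.372              0.066          0.479         2.29
       0.2     0.2                 1.672              0.524          0.493         2.33
       0.2     0.4                10.772              1.000          0.508         2.37
```

With no bias the mean R² sits at the analytic null value 1/299 ≈ 0.33%
(0.37% here at 500 populations) and the coefficient is significant in
about 5% of populations; the zero rows are identical because either knob
at 0 makes the injection the identity.  Mean scores barely move — the
ratio shifts from 0.479 to 0.508 even at the strongest bias — yet at 20%
of subjects and 40% of items *every* population shows a significant
ERI–GHQ association with a mean R² near 11%: a small, plausible-looking
mean shift can carry a large spurious correlation.

```r
interpret_r2(6, grid)
#> band: possibly_na_unlikely
#> minimal reaching cells (log-ratio model): p = 0.20, q = 0.40
```

An observed 6% explained variance falls in the "possibly NA, though
unlikely" band; on this coarse grid only the strongest bias condition
reaches it for the single-predictor models.

A command-line wrapper is installed alongside the package:

```sh
nabiassim calibrate --out marginals.csv
nabiassim run --n-populations 1000 --seed 42 --out-dir results
nabiassim interpret --r2 6 --grid results/results_long.csv
```

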