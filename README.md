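# actipair

Compare wearable-tracker physical activity with questionnaire
self-report, and ask which better predicts body-mass index.

Consumer trackers log minute-by-minute step counts under free-living
conditions; recall questionnaires such as the IPAQ short form ask for
days/week and minutes/day of walking, moderate and vigorous activity
plus sitting over the same 7 days. The two disagree in systematic ways
— self-report inflates higher intensities and understates walking and
sitting — and measurement error attenuates regression coefficients
toward zero, so the instrument with less noise should show stronger
associations with health outcomes. `actipair` implements the full
analysis pipeline for this comparison:

* **Minute-level step processing** — artifact recoding (>200 steps/min
  → missing), nonwear detection (≥120 contiguous zero-step minutes),
  cadence-based intensity classification (sedentary 0–9, walking
  10–100, moderate 101–130, vigorous 131–200 steps/min), day adequacy
  (≥10 h wear) and weekly summaries (steps/d, intensity times, wear
  time).
* **IPAQ cleaning and scoring** — protocol rules (10-min episode
  floor, 180-min daily cap, >960 min/day invalid) and MET-weighted
  scoring (3.3 / 4.0 / 8.0) into MET-h/wk.
* **Cohort assembly** — pairing each recall window with the same 7
  device days, BMI attachment by 90/365-day proximity windows with a
  median merge of calculated and self-reported values, closest-record
  covariate attachment, seasons, analysis-set construction.
* **Comparative statistics** — Spearman correlations, exact Wilcoxon
  matched-pairs signed-rank tests, Cuzick-type trend tests across
  activity categories, and cluster-robust linear regressions of BMI:
  12 separate + 6 combined model families × 3 adjustment tiers, in
  natural and standardized units, with Wald comparisons of device
  versus self-report coefficients (stacked-system construction for
  separate models) and exclusion sensitivity analyses.
* **A synthetic cohort generator** — bout-structured minute traces
  with nonwear and artifacts, recall-biased self-report, covariates,
  and a BMI outcome with configured activity effects and a
  participant-level random intercept, all deterministic under a seed
  and accompanied by a truth ledger.

The core model is linear regression of untransformed BMI on an activity
measure `x` with covariates `Z`,

    BMI_ij = β x_ij + γ' Z_ij + ε_ij,

estimated by least squares with cluster-robust (sandwich) standard
errors grouped by participant `i` (observations `j` repeat within
participants) and the small-sample factor `G/(G−1)·(N−1)/(N−K)`. The
device-vs-self-report contrast `β_device − β_selfreport` is Wald-tested
within a combined model, or across separate models re-estimated as a
stacked system sharing the cluster covariance. Under classical
measurement error, `plim β̂ = β·σ²_x/(σ²_x+σ²_e)` — the noisier
instrument is attenuated, which is the mechanism the package's
simulations reproduce.

## Worked example

```r
library(actipair)
library(dplyr)

cohort <- generate_cohort(sim_config(n_participants = 300), seed = 42)
obs <- cohort$observations

# agreement between paired measures, first observation per participant
compare_measures(filter(obs, observation_rank == 1))
#> # A tibble: 6 × 8
#>   measure   spearman_rho spearman_p wilcoxon_v wilcoxon_p fitbit_median ipaq_median     n
#> 1 sedentary       0.0263   6.50e- 1       571    1.74e-48        99.6       35.5      300
#> 2 walking         0.454    1.14e-16         1    6.14e-51        15.7        2.62     300
#> 3 moderate        0.668    4.08e-40     25028.   5.01e- 2         1.16       1.17     300
#> 4 vigorous        0.813    4.67e-72     25693    9.59e-36         0.333      0.717    300
#> 5 active          0.655    3.31e-38         0    6.08e-51        17.4        5.16     300
#> 6 overall         0.508    4.71e-21        NA   NA             8631.        21.4     300
```

The synthetic cohort reproduces the qualitative discrepancy pattern:
self-reported walking (2.6 h/wk) and sitting (35.5 h/wk) sit far below
the device's 15.7 and 99.6 h/wk, while self-reported vigorous time
exceeds the device's, and the paired signed-rank tests reject equality
for every same-unit measure. Overall activity (steps/d vs MET-h/wk)
correlates at ρ ≈ 0.51.

```r
battery <- fit_model_battery(obs)
battery
#> <model_battery> 54 models (6 measures x 3 tiers), 36 Wald comparisons

filter(battery$comparisons, measure == "vigorous", tier == "full")
#> # A tibble: 2 × 8
#>   measure  tier  fitbit_beta ipaq_beta difference wald_statistic p_value model_mode
#> 1 vigorous full        -2.11    -0.233      -1.88           6.22  0.0126 separate
#> 2 vigorous full        -2.78     0.227      -3.01           4.48  0.0344 combined
```

An hour per week of device-measured vigorous activity predicts a much
larger BMI difference than an hour of self-reported vigorous activity
(−2.11 vs −0.23 kg/m² in this synthetic cohort's fully adjusted
separate models), and the Wald test rejects equality of the two
coefficients — the attenuation signature the package exists to study.
`tidy(battery)` returns the full coefficient table, `autoplot(battery)`
a forest plot, and `run_sensitivity(obs, "mobiletrack")` repeats the
analysis without phone-derived step counts.

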