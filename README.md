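# antdol

Quantifying division of labour (DOL) in colony defence from automated
tracking and behavioural event annotation.

## The problem

When a social insect colony is threatened, do all workers defend equally,
or do a few specialists carry the task? Answering this requires per-ant
measurements in a colony context: who encounters the intruder, who
actually attacks upon encountering it, how consistent individuals are
across repeated trials, and whether apparent group-size effects on
behavioural variation are real or mere sampling artefacts. `antdol`
implements this analysis chain for experiments in the style of clonal
raider ant (*Ooceraea biroi*) colony-defence assays: colonies of 4 or 8
near-identical workers under three brood treatments, a one-hour tracked
baseline (20 fps, 5 cm arena), and three 20-minute defence trials with
annotated encounter and sting events.

## What it computes

* **Defence score** per ant and trial (and pooled across trials):

  `score = (n_stings / n_encounters) × ln(1 + sting_seconds)`

  — the propensity to attack per contact, weighted by log total sting
  duration; 0 for ants that never encountered the intruder. The simpler
  `norm_sting_rate = n_stings / n_encounters` is reported alongside.
* **Baseline exploration and activity**: occupancy-grid Shannon entropy
  `H = −Σ p(x) log₂ p(x)` over a 25 × 25 grid of 2 mm cells, proportion
  of frames moving faster than 1 mm/s, and mean active-bout duration.
* **DOL statistics**: within-colony score ranks (ties share the lowest
  rank), Spearman rank consistency between successive trials per group
  size / brood stratum with Benjamini–Hochberg correction and a
  no-defence exclusion rule, and within-colony behavioural variation
  (sample SD of member scores).
* **Group-size resampling null**: 95% CI of the mean variation of
  pseudo-colonies of 4 resampled (1000×) from size-8 colonies, against
  which observed small-colony variation is compared.
* **Colony defence efficiency**: total stings received by the intruder.
* **Synthetic experiments**: a generative model (heterogeneous Hill-type
  response thresholds, two-state movement, optional activity–aggression
  coupling) producing trajectory, event and design tables with the
  statistical structure the analysis assumes.

Trajectory preprocessing (speed-based aberrance detection, linear
interpolation of short gaps) and tidy model-ready exports for external
GLMM fitting are included; model fitting itself is out of scope.

## Worked example

```r
library(antdol)

defence_score(13, 18, 629.25)
#> [1] 4.655529        # a highly defensive ant: 13 stings / 18 encounters

sc <- sim_scenario(seed = 42)                  # 6 treatments x 6 colonies
ex <- simulate_experiment(sc, include_baseline = FALSE)
roster  <- ex$individuals[, c("colony_id", "ant_id")]
records <- defence_records(ex$events, roster)

consistency_analysis(records, ex$design, stratify_by = "group_size")
#>   stratum_var stratum trial_pair   rho        p    p_adj     n n_colonies
#> 1 group_size  4       1-2        0.822 8.45e-19 1.13e-18    72         18
#> 2 group_size  4       2-3        0.789 1.89e-16 1.89e-16    72         18
#> 3 group_size  8       1-2        0.762 1.35e-28 2.69e-28   144         18
#> 4 group_size  8       2-3        0.834 1.51e-38 6.04e-38   144         18
```

Positive `rho` with small adjusted p-values: individuals keep their
defence ranks across trials, i.e. consistent DOL under the default
strongly heterogeneous response thresholds (`threshold_sd = 1`). Setting
`threshold_sd = 0` collapses the consistency to noise around zero.

```r
res <- resample_variation(records, ex$design, seed = 42)
compare_observed(res, records, ex$design)
#> <antdol_resample> 1000 iterations, 18 colonies of 8 -> pseudo-colonies of 4
#>   95% CI of mean variation: (2.0856, 2.6397)
#>   observed small-colony mean: 2.3153 (inside CI)
```

Here the observed size-4 variation falls inside the CI — as it should,
since these simulated small colonies draw from the same trait
distribution as the large ones and differ by sampling alone.

The full pipeline (simulate → preprocess → metrics → score → dol →
resample, with a reproducibility manifest) runs from one config:

```r
run_pipeline(pipeline_config(scenario = list(seed = 42)), "out/")
```

or from a shell via `inst/cli/antdol.R` (subcommands `simulate`,
`preprocess`, `metrics`, `score`, `dol`, `resample`, `run-all`).

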