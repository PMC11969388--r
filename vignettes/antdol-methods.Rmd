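---
title: "Quantifying division of labour in colony defence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying division of labour in colony defence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antdol)
```

## The measurement problem

Social insect colonies divide labour: some workers consistently do a task
that others consistently avoid. Colony defence is a striking case, but in
most species inter-individual differences in morphology, age or genotype
confound the question of whether division of labour (DOL) can emerge among
*equivalent* workers. The clonal raider ant (*Ooceraea biroi*) removes
those confounds — colonies are queenless, workers are near-clonal and
age-matched — which makes it the reference system this package is designed
around: small experimental colonies (4 or 8 workers, with no brood, larvae
or pupae), one hour of baseline video tracking at 20 fps in a 5 cm Petri
dish, followed by three 20-minute defence trials in which a freeze-killed
allospecific worker is introduced and every encounter and stinging attempt
is annotated per ant.

`antdol` implements the full quantitative chain for such experiments:

1. trajectory preprocessing (missing/aberrant detections),
2. baseline exploration and activity metrics,
3. per-ant defence scoring,
4. DOL statistics — inter-trial rank consistency and within-colony
   behavioural variation,
5. a subsampling null separating true group-size effects from sampling
   effects,
6. a synthetic-colony generator so that every stage is testable without
   any external data.

## Defence score

For each ant and trial (and pooled over trials),

$$\mathrm{score} \;=\; \frac{n_\text{stings}}{n_\text{encounters}}
  \times \ln\!\left(1 + d_\text{sting}\right),$$

where $d_\text{sting}$ is the summed duration (s) of the ant's stinging
attempts. Normalising by encounters isolates the *propensity* to attack
upon contact from variation in encounter rates; the logarithm keeps very
long stinging bouts from dominating. An ant with no encounters is assigned
score 0. The logarithm is natural: with the documented example aggregates
(13 stings in 18 encounters, 629.25 s), $\tfrac{13}{18}\ln(630.25) = 4.66$
to two decimals, which only the natural log reproduces. Pooled scores
apply the formula once to pooled sums, not to averaged per-trial scores.
The count ratio may exceed 1 (several stinging attempts within one
contact); no deduplication window is applied because events come from
manual annotation with no stated merging rule.

## Baseline exploration and activity

The arena bounding square is gridded into $25 \times 25$ cells of
$2\,\mathrm{mm}$ (about one body length). Exploration is the Shannon
entropy of the occupancy distribution,
$H = -\sum_x p(x)\log_2 p(x)$, in bits: 0 for an ant that never leaves
one cell, $\log_2 625 \approx 9.288$ for uniform coverage. Base 2 is used
because published per-ant values (e.g. $H = 8.415$) exceed the
natural-log maximum $\ln 625 \approx 6.44$, so a natural-log convention
cannot be the intended one.

Activity uses per-frame speed (displacement from the previous frame times
fps). A frame is *active* when speed exceeds 1 mm/s strictly; the first
frame of every contiguous segment has no predecessor and is excluded from
the denominator. `prop_active` is the active fraction of classified
frames; active bouts are maximal runs of active frames (never spanning a
tracking gap) and `mean_bout` is their mean length in seconds, 0 when
there is no bout. No speed smoothing is applied.

## Preprocessing contract

Tracking pipelines emit missing detections and occasional identity-swap
jumps. `preprocess_trajectories()` applies a declared, config-exposed
stand-in for the usual cleanup: a sequential scan marks a position
aberrant when the straight-line speed from the last *accepted* position
exceeds `v_max` (default 50 mm/s, roughly 20 body lengths per second;
elapsed time accounts for intervening missing frames, so an isolated jump
removes only the jumped frame); missing runs of at most `max_gap` frames
(default 10 = 0.5 s) bounded by valid fixes are linearly interpolated;
longer runs are removed. Every frame is classified exactly once
(kept / interpolated / removed) and the per-ant report proves the
bookkeeping. Because interpolated segments lie on the chord between
accepted fixes, their speeds cannot exceed `v_max`, which makes the
operation idempotent. Interpolated frames carry positions and are included
in the activity denominator; their count is reported so users can apply a
stricter convention.

## DOL statistics

**Consistency.** Scores are ranked within each colony and trial, ties
sharing the *lowest* rank (the display and pooling convention). For each
stratum (each group size, or separately each brood treatment) the ranks of
all member ants are pooled across colonies and Spearman's rank correlation
is computed between successive trials (1 vs 2, 2 vs 3). The coefficient is
the standard tie-corrected statistic (Pearson correlation of average
ranks) — min-rank display and a tie-corrected coefficient are not in
conflict, and both behaviours are switchable (`pool_ranks`). p-values use
the t approximation, with an exact permutation option for $n \le 8$; the
family of tests from one stratification is adjusted with
Benjamini–Hochberg. Colonies with zero sting events in both trials of a
pair carry no defence information for that pair and are excluded. Pooling
ants across colonies (rather than averaging per-colony coefficients) is
the implemented reading, consistent with one reported coefficient per
stratum-pair; a per-colony analysis can be run by filtering the records.

**Variation.** Within-colony behavioural variation is the sample standard
deviation ($n-1$) of member scores, per trial and pooled. Model fitting on
these summaries (GLMM/LM, term reduction, post hoc contrasts) is
deliberately out of scope: `assemble_model_tables()` exports tidy
colony-trial and per-ant tables for `lme4`/`glmmTMB` and friends.

**Group-size null.** Larger colonies can show larger score SDs simply
because more draws from a skewed distribution spread further. The
resampling control builds pseudo-colonies of 4 by drawing members without
replacement from each size-8 colony (one subsample per colony per
iteration — the implemented reading of "averaged across replicate
simulated colonies"), averages pseudo-colony SDs, repeats 1000 times, and
takes the 2.5th/97.5th percentiles of the iteration means as a closed 95%
interval. An observed small-colony mean outside the interval indicates a
group-size effect beyond sampling. Because in the default design each
colony has only $\binom{8}{4} = 70$ distinct subsets, the implementation
enumerates all subset SDs once and draws among them, which is
distributionally identical to resampling members and fast enough for
calibration studies; a generic sampling path covers larger designs. The
resampled quantity is the pooled-across-trials SD by default (`trial`
switches this).

## The synthetic-colony generator

The generator is a first-class module: it encodes the statistical
structure the analysis assumes, so downstream stages can be validated
end-to-end.

**Traits.** Each ant carries a response threshold $\theta_i$ (log-normal,
median `threshold_mean`, log-SD `threshold_sd`) and an activity propensity
$a_i$ (log-normal, median 1, log-SD `activity_sd`), drawn from a bivariate
normal on the log scale with correlation $-\,$`coupling`. Positive
coupling therefore makes more-active ants more aggressive; the default
`coupling = 0` encodes the *absence* of an exploration–aggression
syndrome, which is the regime the package treats as its default study
condition.

**Defence trials.** Encounters arrive per ant as a Poisson process at
`encounter_rate_scale` $\times\, a_i$ per minute — activity drives
encounter rate, reflecting that exploratory ants meet the intruder while
patrolling. At each encounter the ant stings with the fixed-threshold
Hill response
$p_i = s^h / (s^h + \theta_i^h)$ (stimulus $s$, steepness $h$), the
classic response-threshold model of task allocation; the functional form
is a design choice, since threshold variation is named as mechanism in
this literature without a stated form. Sting durations are exponential
(one-parameter, positive support), truncated at trial end.

**Baseline movement.** A two-state Markov walk: per-frame switching
probabilities `p_active_on`$\times a_i$ and `p_active_off`$/ a_i$, active
steps of length `speed_active_mean`$\times a_i / \mathrm{fps}$ with
heading diffusion `turn_sd`, reflecting circular boundary, stationary
inactive frames. This is the minimal model that yields tunable entropy,
activity fractions and bout lengths. Optional injection of missing frames
and aberrant jumps (default off) exercises preprocessing.

**Default parameter choices.** Values the study design fixes are fixed
here (6 colonies per treatment, sizes {4, 8}, three brood treatments,
3 × 1200 s trials, 3600 s baseline, 20 fps, 50 mm arena). Generative
values no study table states were chosen once, from the magnitudes the
reference aggregates imply, and are not tuned thereafter:

| parameter | default | rationale |
|---|---|---|
| `encounter_rate_scale` | 0.75 min⁻¹ | ≈ 15 encounters per 20-min trial at median activity; documented per-trial counts of 14–18 |
| `sting_duration_mean` | 45 s | 629.25 s over 13 attempts ≈ 48 s per attempt |
| `threshold_mean`, `stimulus` | 1, 1 | stimulus at the median threshold: median ant stings at half its encounters |
| `threshold_sd` | 1.0 | strong threshold heterogeneity — the mechanism under study |
| `threshold_steepness` | 2 | gentle sigmoid; keeps $p_i$ spread over (0, 1) |
| `activity_sd` | 0.15 | modest movement heterogeneity relative to threshold heterogeneity: the defence score's $\ln(1+d)$ term is not encounter-normalised, so total sting duration grows with encounter count and leaks a small positive activity–score association; movement heterogeneity must remain the minor variance component for the no-syndrome default to hold, as it does in the reference system |
| `p_active_on`, `p_active_off` | 0.01, 0.02 | mean active bouts of ~2.5 s, one-third of time active at median |
| `speed_active_mean` | 5 mm/s | typical ant walking speed; well above the 1 mm/s activity cutoff |
| `turn_sd` | 0.6 rad | persistent but diffusive paths that fill the arena over minutes |

**What the generator does not emulate.** No brood-pile geometry or
wall-following (real occupancy grids are strongly inhomogeneous), no
intruder movement (the reference design uses a dead intruder on purpose),
no social amplification (alarm pheromones make real defence responses
interdependent), no annotation noise, and encounter rates held constant
across trials (nothing in the reference design says they varied).
Passing tests therefore validate the *statistical machinery* — scoring,
ranking, exclusion rules, null calibration — not ecological realism of
any particular dataset.

## Numerical and replication choices

* Frames are 0-based; time = frame / fps; coordinates are arena-centred
  (readers accept an offset for corner-origin pixels).
* Positions outside the grid square are clamped to edge cells and
  counted (`n_clamped`), rather than dropped.
* Zero variance in either rank vector leaves Spearman's rho undefined
  (`NA`), never 0; strata with fewer than 3 usable ants are flagged
  not-computable.
* CI bounds are closed: an observed value exactly on a bound is inside.
* Determinism: a scenario seed fixes every simulated table bit-for-bit;
  the pipeline manifest records the config hash and seed and carries no
  timestamps, so reruns are byte-identical.
* Replicate suites in the package's tests run 200-replicate experiments
  at the full 6 × 6 design for event-based statistics, and use a 300 s
  baseline (6000 frames per ant) where trajectories are needed: entropy
  and activity *ranks* stabilise well before five minutes of simulated
  recording, and the replicate suites compare ranks, not absolute
  entropies. Single-scenario tests of the trajectory machinery use the
  full one-hour contract.

## Worked example

```{r example, eval = FALSE}
sc <- sim_scenario(seed = 42)
ex <- simulate_experiment(sc, include_baseline = FALSE)
roster <- ex$individuals[, c("colony_id", "ant_id")]
records <- defence_records(ex$events, roster)

consistency_analysis(records, ex$design, stratify_by = "group_size")
behavioural_variation(records)

res <- resample_variation(records, ex$design, seed = 42)
compare_observed(res, records, ex$design)
```

## Known limitations

* The aberrance scan is greedy: after a long occlusion the first
  redetected position is accepted relative to the pre-occlusion anchor,
  which can mask a jump that happens exactly during the gap.
* The defence score's duration term is not encounter-normalised (by
  design, matching its published definition); users comparing very
  heterogeneous encounter counts should inspect `norm_sting_rate`
  alongside it.
* The exact permutation p-value enumerates $n!$ permutations and is
  limited to $n \le 8$; pooled strata use the t approximation.
* `colony_mean_scores()` and the resampling assume complete member
  records; partial colonies are a hard error, not silently dropped.
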