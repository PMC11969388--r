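test_that("scenario validation rejects ill-formed parameters", {
  expect_s3_class(sim_scenario(), "antdol_scenario")
  expect_error(sim_scenario(threshold_sd = -0.1), "non-negative")
  expect_error(sim_scenario(coupling = 1.2), "coupling")
  expect_error(sim_scenario(trial_duration = 0), "positive")
  expect_error(sim_scenario(fps = -20), "positive")
  expect_error(sim_scenario(missing_rate = 1), "probabilities")
  expect_error(sim_scenario(p_active_on = 0, p_active_off = 0),
               "cannot both be 0")
})

test_that("design table expands the factorial design with unique colonies", {
  d <- design_table(sim_scenario())
  expect_equal(nrow(d), 6 * 2 * 3)
  expect_false(anyDuplicated(d$colony_id) > 0)
  expect_equal(sort(unique(d$group_size)), c(4L, 8L))
  expect_setequal(unique(d$brood), c("none", "larvae", "pupae"))
  expect_equal(sum(d$group_size == 4 & d$brood == "pupae"), 6)
})

test_that("zero threshold spread collapses thresholds to the median", {
  sc <- sim_scenario(threshold_sd = 0, threshold_mean = 2.5)
  set.seed(1)
  ants <- draw_individuals(sc, "C01", 8)
  expect_equal(ants$threshold, rep(2.5, 8))
})

test_that("trait coupling controls the activity-aggression correlation", {
  set.seed(101)
  sc0 <- sim_scenario(coupling = 0)
  ants <- draw_individuals(sc0, "C01", 10000)
  expect_lt(abs(cor(ants$activity, log(ants$threshold))), 0.05)

  sc9 <- sim_scenario(coupling = 0.9)
  ants9 <- draw_individuals(sc9, "C01", 10000)
  expect_lt(abs(cor(ants9$activity, -log(ants9$threshold)) - 0.9), 0.05)
})

test_that("sting probability is the Hill threshold response", {
  expect_equal(sting_probability(1, 1, 2), 0.5)
  expect_equal(sting_probability(1, 1, 37), 0.5)
  expect_equal(sting_probability(2, 1, 1), 2 / 3)
  # steep threshold, stimulus below threshold: response vanishes
  expect_lt(sting_probability(0.5, 1, 200), 1e-50)
})

test_that("simulated sting fraction converges to the threshold response", {
  # stimulus equal to every threshold: half of ~10000 encounters sting
  sc <- sim_scenario(threshold_sd = 0, activity_sd = 0,
                     encounter_rate_scale = 500, seed = 5)
  set.seed(5)
  ants <- draw_individuals(sc, "C01", 1)
  ev <- simulate_defence_trial(sc, ants, 1)
  n_enc <- sum(ev$event_type == "encounter")
  n_sting <- sum(ev$event_type == "sting")
  expect_gt(n_enc, 9000)
  expect_lt(abs(n_sting / n_enc - 0.5), 0.02)
})

test_that("a steep threshold above the stimulus suppresses all stings", {
  sc <- sim_scenario(threshold_sd = 0, activity_sd = 0, threshold_mean = 1,
                     stimulus = 0.5, threshold_steepness = 200,
                     encounter_rate_scale = 50, seed = 8)
  set.seed(8)
  ants <- draw_individuals(sc, "C01", 1)
  ev <- simulate_defence_trial(sc, ants, 1)
  expect_gt(sum(ev$event_type == "encounter"), 900)
  expect_equal(sum(ev$event_type == "sting"), 0)
})

test_that("zero encounter rate yields an empty event table", {
  sc <- sim_scenario(encounter_rate_scale = 0, seed = 2)
  set.seed(2)
  ants <- draw_individuals(sc, "C01", 4)
  ev <- simulate_defence_trial(sc, ants, 1)
  expect_equal(nrow(ev), 0)
  expect_named(ev, c("colony_id", "trial", "ant_id", "event_type", "onset",
                     "offset"))
})

test_that("event tables respect their invariants", {
  sc <- event_scenario(n_colonies_per_treatment = 1, seed = 4)
  ex <- simulate_experiment(sc, include_baseline = FALSE)
  ev <- ex$events
  expect_true(all(ev$onset >= 0))
  expect_true(all(ev$offset >= ev$onset))
  expect_true(all(ev$offset <= sc$trial_duration))
  expect_true(all(ev$trial %in% 1:3))
  expect_true(all(ev$event_type %in% c("encounter", "sting")))
  # stings are nested at their encounter's onset
  st <- ev[ev$event_type == "sting", ]
  enc_keys <- paste(ev$colony_id, ev$trial, ev$ant_id, ev$onset)[
    ev$event_type == "encounter"]
  expect_true(all(paste(st$colony_id, st$trial, st$ant_id, st$onset) %in%
                    enc_keys))
})

test_that("an ant that can never activate never moves", {
  sc <- sim_scenario(p_active_on = 0, baseline_duration = 30, seed = 3)
  set.seed(3)
  ants <- draw_individuals(sc, "C01", 2)
  traj <- simulate_baseline_trajectory(sc, ants)
  speeds <- traj |>
    dplyr::group_by(ant_id) |>
    dplyr::summarise(moved = sum(sqrt(diff(x)^2 + diff(y)^2)) > 0)
  expect_false(any(speeds$moved))
})

test_that("clean baseline trajectories have no gaps and stay in the arena", {
  sc <- tiny_scenario()
  set.seed(sc$seed)
  ants <- draw_individuals(sc, "C01", 4)
  traj <- simulate_baseline_trajectory(sc, ants)
  expect_equal(nrow(traj), 4 * sc$baseline_duration * sc$fps)
  expect_false(anyNA(traj$x))
  expect_true(all(sqrt(traj$x^2 + traj$y^2) <= sc$arena_diameter / 2 + 1e-9))
})

test_that("injection knobs create missing frames and aberrant jumps", {
  sc <- sim_scenario(baseline_duration = 60, missing_rate = 0.05,
                     jump_rate = 0.01, seed = 6)
  set.seed(6)
  ants <- draw_individuals(sc, "C01", 2)
  traj <- simulate_baseline_trajectory(sc, ants)
  expect_gt(sum(is.na(traj$x)), 0)
  sp <- traj[traj$ant_id == ants$ant_id[1], ]
  speed <- sqrt(diff(sp$x)^2 + diff(sp$y)^2) * sc$fps
  expect_gt(max(speed, na.rm = TRUE), 50)
})

test_that("identical seed and scenario reproduce every output bit-for-bit", {
  sc <- tiny_scenario()
  ex1 <- simulate_experiment(sc)
  ex2 <- simulate_experiment(sc)
  expect_identical(ex1$design, ex2$design)
  expect_identical(ex1$individuals, ex2$individuals)
  expect_identical(ex1$trajectories, ex2$trajectories)
  expect_identical(ex1$events, ex2$events)
  ex3 <- simulate_experiment(sim_scenario(n_colonies_per_treatment = 1,
                                          baseline_duration = 10, seed = 12))
  expect_false(identical(ex1$events, ex3$events))
})

test_that("per-ant sting rates converge to the Hill probability", {
  # law-of-large-numbers check at ~10^4 encounters per ant
  sc <- sim_scenario(encounter_rate_scale = 500, activity_sd = 0, seed = 9)
  set.seed(9)
  ants <- draw_individuals(sc, "C01", 5)
  p <- sting_probability(sc$stimulus, ants$threshold,
                         sc$threshold_steepness)
  ev <- simulate_defence_trial(sc, ants, 1)
  agg <- aggregate_events(ev, ants[, c("colony_id", "ant_id")], trials = 1)
  p_hat <- agg$n_stings / agg$n_encounters
  expect_true(all(abs(p_hat - p[match(agg$ant_id, ants$ant_id)]) < 0.02))
})

test_that("stronger threshold heterogeneity raises DOL downstream", {
  # light version of the recovery property (the acceptance suite runs the
  # full replicate design): median within-colony variation grows with
  # threshold_sd
  med_var <- sapply(c(0, 1), function(tsd) {
    vals <- sapply(1:30, function(r) {
      sc <- event_scenario(n_colonies_per_treatment = 1, threshold_sd = tsd,
                           seed = 1000 + r)
      ex <- simulate_experiment(sc, include_baseline = FALSE)
      rec <- defence_records(ex$events,
                             ex$individuals[, c("colony_id", "ant_id")])
      mean(behavioural_variation(rec)$variation[
        behavioural_variation(rec)$trial == "pooled"])
    })
    median(vals)
  })
  expect_gt(med_var[2], med_var[1])
})
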