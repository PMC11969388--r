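#' Draw latent individual traits for one colony
#'
#' Samples per-ant response thresholds and activity propensities from the
#' scenario's joint trait distribution. Thresholds are log-normal with median
#' `threshold_mean` and log-scale spread `threshold_sd`; activity propensities
#' are log-normal with median 1 and log-scale spread `activity_sd`. The two
#' log-traits are drawn from a bivariate normal with correlation
#' `-coupling`, so that positive coupling makes more-active ants more
#' aggressive (lower threshold). Per-ant movement parameters (state-switching
#' probabilities, active speed) are scaled by the activity propensity.
#'
#' Draws consume the current RNG stream; call inside `withr::with_seed()` or
#' after `set.seed()` for reproducibility (as [simulate_experiment()] does).
#'
#' @param scenario an `antdol_scenario`.
#' @param colony_id colony label attached to the output.
#' @param group_size number of ants to draw.
#' @return A tibble with one row per ant: `colony_id`, `ant_id`, `threshold`,
#'   `activity`, `p_on`, `p_off`, `speed_active`.
#' @export
draw_individuals <- function(scenario, colony_id, group_size) {
  validate_scenario(scenario)
  n <- as.integer(group_size)
  stopifnot(n >= 1)
  rho <- -scenario$coupling
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  log_theta <- log(scenario$threshold_mean) + scenario$threshold_sd * z1
  activity <- exp(scenario$activity_sd * z2)
  tibble::tibble(
    colony_id = colony_id,
    ant_id = sprintf("%s_A%02d", colony_id, seq_len(n)),
    threshold = exp(log_theta),
    activity = activity,
    p_on = pmin(1, scenario$p_active_on * activity),
    p_off = pmin(1, pmax(scenario$p_active_off / activity, 1e-6)),
    speed_active = scenario$speed_active_mean * activity
  )
}

#' Hill-type probability of stinging upon one encounter
#'
#' `p = s^h / (s^h + theta^h)`: the classic fixed-threshold response
#' function. Equals 0.5 when the stimulus matches the threshold and sharpens
#' with the steepness exponent `h`.
#'
#' @param stimulus stimulus intensity (scalar or vector).
#' @param threshold per-ant response threshold.
#' @param steepness Hill exponent.
#' @return Sting probabilities in `[0, 1]`.
#' @export
sting_probability <- function(stimulus, threshold, steepness) {
  sh <- stimulus^steepness
  sh / (sh + threshold^steepness)
}

#' Simulate one ant-hour of baseline trajectory
#'
#' Runs the two-state correlated random walk for every ant of a colony for
#' the scenario's baseline duration: active frames move at the ant's active
#' speed with diffusing heading inside the circular arena (reflecting
#' boundary); inactive frames are stationary. Optional per-frame injection of
#' missing detections (`missing_rate`) and aberrant position jumps
#' (`jump_rate`) exercises downstream preprocessing; both default to 0.
#'
#' @param scenario an `antdol_scenario`.
#' @param individuals latent trait tibble from [draw_individuals()].
#' @param n_frames number of frames; defaults to
#'   `baseline_duration * fps`.
#' @return A trajectory tibble: `colony_id`, `ant_id`, `frame` (0-based),
#'   `x`, `y` (mm, arena-centred; `NA` for missing detections).
#' @export
simulate_baseline_trajectory <- function(scenario, individuals,
                                         n_frames = NULL) {
  validate_scenario(scenario)
  if (is.null(n_frames)) {
    n_frames <- round(scenario$baseline_duration * scenario$fps)
  }
  n_frames <- as.integer(n_frames)
  radius <- scenario$arena_diameter / 2
  step_scale <- 1 / scenario$fps
  out <- vector("list", nrow(individuals))
  for (i in seq_len(nrow(individuals))) {
    ant <- individuals[i, ]
    # random start inside the arena (uniform over the disc)
    r0 <- radius * sqrt(runif(1))
    a0 <- runif(1, 0, 2 * pi)
    w <- walk_cpp(n_frames, r0 * cos(a0), r0 * sin(a0),
                  ant$p_on, ant$p_off,
                  ant$speed_active * step_scale, scenario$turn_sd, radius)
    x <- w$x
    y <- w$y
    if (scenario$jump_rate > 0) {
      jump <- runif(n_frames) < scenario$jump_rate
      nj <- sum(jump)
      if (nj > 0) {
        rj <- radius * sqrt(runif(nj))
        aj <- runif(nj, 0, 2 * pi)
        x[jump] <- rj * cos(aj)
        y[jump] <- rj * sin(aj)
      }
    }
    if (scenario$missing_rate > 0) {
      miss <- runif(n_frames) < scenario$missing_rate
      x[miss] <- NA_real_
      y[miss] <- NA_real_
    }
    out[[i]] <- tibble::new_tibble(list(
      colony_id = rep(ant$colony_id, n_frames),
      ant_id = rep(ant$ant_id, n_frames),
      frame = seq_len(n_frames) - 1L,
      x = x,
      y = y
    ), nrow = n_frames)
  }
  dplyr::bind_rows(out)
}

#' Simulate one colony-defence trial
#'
#' Per ant, intruder encounters arrive as a Poisson process with rate
#' `encounter_rate_scale * activity` per minute over the trial. At each
#' encounter the ant stings with its Hill-type probability
#' ([sting_probability()]); sting durations are exponential with mean
#' `sting_duration_mean`, truncated at the trial end. Encounters are point
#' events (`onset == offset`); each sting is nested at its encounter's onset.
#'
#' @param scenario an `antdol_scenario`.
#' @param individuals latent trait tibble from [draw_individuals()].
#' @param trial trial index in `1:n_trials`.
#' @return An event tibble: `colony_id`, `trial`, `ant_id`, `event_type`
#'   (`"encounter"` or `"sting"`), `onset`, `offset` (seconds from trial
#'   start), sorted by onset.
#' @export
simulate_defence_trial <- function(scenario, individuals, trial) {
  validate_scenario(scenario)
  trial <- as.integer(trial)
  stopifnot(trial >= 1, trial <= scenario$n_trials)
  dur <- scenario$trial_duration
  p_sting <- sting_probability(scenario$stimulus, individuals$threshold,
                               scenario$threshold_steepness)
  rate <- scenario$encounter_rate_scale * individuals$activity / 60
  n_enc <- rpois(nrow(individuals), rate * dur)
  idx <- rep(seq_len(nrow(individuals)), n_enc)
  t_enc <- runif(length(idx), 0, dur)
  stings <- runif(length(idx)) < p_sting[idx]
  d_st <- rexp(sum(stings), 1 / scenario$sting_duration_mean)
  all_idx <- c(idx, idx[stings])
  event_type <- rep(c("encounter", "sting"), c(length(idx), sum(stings)))
  onset <- c(t_enc, t_enc[stings])
  offset <- c(t_enc, pmin(t_enc[stings] + d_st, dur))
  ant_id <- individuals$ant_id[all_idx]
  o <- order(onset, event_type, ant_id)
  tibble::new_tibble(list(
    colony_id = individuals$colony_id[all_idx][o],
    trial = rep(trial, length(o)),
    ant_id = ant_id[o],
    event_type = event_type[o],
    onset = onset[o],
    offset = offset[o]
  ), nrow = length(o))
}

#' Simulate a full colony-defence experiment
#'
#' Expands the scenario design, draws latent traits for every colony, and
#' simulates the baseline hour (optional) and all defence trials. The
#' scenario seed is set once at entry, so identical scenarios yield
#' bit-identical outputs.
#'
#' @param scenario an `antdol_scenario`.
#' @param include_baseline simulate baseline trajectories? Event-only
#'   analyses (scoring, DOL, resampling) can skip them for speed.
#' @return A list with elements `design` (tibble), `individuals` (latent
#'   traits, one row per ant), `trajectories` (tibble or `NULL`), `events`
#'   (tibble over all colonies and trials).
#' @examples
#' sc <- sim_scenario(n_colonies_per_treatment = 1, baseline_duration = 5,
#'                    seed = 7)
#' ex <- simulate_experiment(sc)
#' nrow(ex$design)
#' @export
simulate_experiment <- function(scenario, include_baseline = TRUE) {
  validate_scenario(scenario)
  set.seed(scenario$seed)
  design <- design_table(scenario)
  indiv <- vector("list", nrow(design))
  traj <- if (include_baseline) vector("list", nrow(design)) else NULL
  events <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ants <- draw_individuals(scenario, design$colony_id[i],
                             design$group_size[i])
    indiv[[i]] <- ants
    if (include_baseline) {
      traj[[i]] <- simulate_baseline_trajectory(scenario, ants)
    }
    ev <- lapply(seq_len(scenario$n_trials), function(tr) {
      simulate_defence_trial(scenario, ants, tr)
    })
    events[[i]] <- dplyr::bind_rows(ev)
  }
  list(
    design = design,
    individuals = dplyr::bind_rows(indiv),
    trajectories = if (include_baseline) dplyr::bind_rows(traj) else NULL,
    events = dplyr::bind_rows(events)
  )
}
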