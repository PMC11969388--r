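#' Define a synthetic colony-defence experiment
#'
#' A scenario bundles every generative parameter of the synthetic experiment:
#' the factorial design (group sizes x brood treatments x replicates), the
#' recording geometry, the response-threshold model governing stinging, and
#' the two-state movement model governing baseline trajectories. The defaults
#' reproduce the study conditions the package is built around: 6 replicate
#' colonies per treatment, group sizes 4 and 8, three brood treatments, a 1 h
#' baseline recorded at 20 fps in a 5 cm circular arena, and three 20 min
#' defence trials.
#'
#' Individual heterogeneity enters through two latent per-ant traits: a
#' response threshold (log-normal around `threshold_mean` with log-scale
#' spread `threshold_sd`) and an activity propensity (log-normal with
#' log-scale spread `activity_sd`). `coupling` sets the correlation between
#' activity and aggression (positive coupling: more-active ants have lower
#' thresholds); the default 0 encodes the absence of an exploration-defence
#' behavioural syndrome.
#'
#' @param n_colonies_per_treatment replicate colonies per treatment cell.
#' @param group_sizes integer vector of colony sizes.
#' @param brood_treatments character vector of brood treatment labels.
#' @param n_trials number of defence trials.
#' @param trial_duration defence trial length, seconds.
#' @param baseline_duration baseline recording length, seconds.
#' @param fps frames per second of the recording.
#' @param arena_diameter arena diameter, mm.
#' @param threshold_mean median response threshold, stimulus units.
#' @param threshold_sd between-individual log-scale threshold spread
#'   (0 switches heterogeneity off).
#' @param threshold_steepness Hill exponent of the threshold response.
#' @param stimulus stimulus intensity of one intruder encounter.
#' @param encounter_rate_scale encounters per minute per unit activity
#'   propensity (0 yields no encounters).
#' @param sting_duration_mean mean duration of one stinging attempt, seconds.
#' @param p_active_on,p_active_off per-frame switching probabilities of the
#'   inactive -> active and active -> inactive transitions at unit activity
#'   propensity.
#' @param speed_active_mean movement speed while active at unit activity
#'   propensity, mm/s.
#' @param activity_sd between-individual log-scale spread of the activity
#'   propensity.
#' @param turn_sd per-frame heading diffusion of the active walk, radians.
#' @param coupling correlation in `[-1, 1]` between activity propensity and
#'   aggression (negative log threshold).
#' @param missing_rate,jump_rate per-frame probabilities of injecting a
#'   missing detection or an aberrant position jump into baseline
#'   trajectories (both default 0; used to exercise preprocessing).
#' @param seed integer seed fixing every draw of the experiment.
#'
#' @return An object of class `antdol_scenario` (a validated named list).
#' @examples
#' sc <- sim_scenario(n_colonies_per_treatment = 1, baseline_duration = 10)
#' design_table(sc)
#' @export
sim_scenario <- function(n_colonies_per_treatment = 6,
                         group_sizes = c(4L, 8L),
                         brood_treatments = c("none", "larvae", "pupae"),
                         n_trials = 3,
                         trial_duration = 1200,
                         baseline_duration = 3600,
                         fps = 20,
                         arena_diameter = 50,
                         threshold_mean = 1,
                         threshold_sd = 1,
                         threshold_steepness = 2,
                         stimulus = 1,
                         encounter_rate_scale = 0.75,
                         sting_duration_mean = 45,
                         p_active_on = 0.01,
                         p_active_off = 0.02,
                         speed_active_mean = 5,
                         activity_sd = 0.15,
                         turn_sd = 0.6,
                         coupling = 0,
                         missing_rate = 0,
                         jump_rate = 0,
                         seed = 1L) {
  sc <- list(
    n_colonies_per_treatment = as.integer(n_colonies_per_treatment),
    group_sizes = as.integer(group_sizes),
    brood_treatments = as.character(brood_treatments),
    n_trials = as.integer(n_trials),
    trial_duration = trial_duration,
    baseline_duration = baseline_duration,
    fps = fps,
    arena_diameter = arena_diameter,
    threshold_mean = threshold_mean,
    threshold_sd = threshold_sd,
    threshold_steepness = threshold_steepness,
    stimulus = stimulus,
    encounter_rate_scale = encounter_rate_scale,
    sting_duration_mean = sting_duration_mean,
    p_active_on = p_active_on,
    p_active_off = p_active_off,
    speed_active_mean = speed_active_mean,
    activity_sd = activity_sd,
    turn_sd = turn_sd,
    coupling = coupling,
    missing_rate = missing_rate,
    jump_rate = jump_rate,
    seed = as.integer(seed)
  )
  class(sc) <- "antdol_scenario"
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "antdol_scenario"))
  pos <- c("n_trials", "trial_duration", "baseline_duration", "fps",
           "arena_diameter", "threshold_mean", "threshold_steepness",
           "stimulus", "sting_duration_mean",
           "speed_active_mean", "turn_sd", "n_colonies_per_treatment")
  for (f in pos) {
    if (!is.numeric(sc[[f]]) || length(sc[[f]]) != 1 || !is.finite(sc[[f]]) ||
        sc[[f]] <= 0) {
      stop("scenario field '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  nonneg <- c("threshold_sd", "activity_sd", "encounter_rate_scale",
              "missing_rate", "jump_rate", "p_active_on", "p_active_off")
  for (f in nonneg) {
    if (!is.numeric(sc[[f]]) || length(sc[[f]]) != 1 || !is.finite(sc[[f]]) ||
        sc[[f]] < 0) {
      stop("scenario field '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (sc$coupling < -1 || sc$coupling > 1) {
    stop("coupling must lie in [-1, 1]", call. = FALSE)
  }
  if (any(sc$group_sizes < 1)) stop("group sizes must be positive", call. = FALSE)
  if (anyDuplicated(sc$group_sizes)) stop("duplicate group sizes", call. = FALSE)
  if (anyDuplicated(sc$brood_treatments)) {
    stop("duplicate brood treatments", call. = FALSE)
  }
  if (sc$missing_rate >= 1 || sc$jump_rate >= 1 ||
      sc$p_active_on > 1 || sc$p_active_off > 1) {
    stop("per-frame probabilities must not exceed 1", call. = FALSE)
  }
  if (sc$p_active_on + sc$p_active_off == 0) {
    stop("p_active_on and p_active_off cannot both be 0", call. = FALSE)
  }
  sc
}

#' @export
print.antdol_scenario <- function(x, ...) {
  cat("<antdol_scenario>\n")
  cat(sprintf("  design: %d colonies/treatment x sizes {%s} x brood {%s}\n",
              x$n_colonies_per_treatment,
              paste(x$group_sizes, collapse = ","),
              paste(x$brood_treatments, collapse = ",")))
  cat(sprintf("  recording: %g s baseline @ %g fps, %d x %g s trials, arena %g mm\n",
              x$baseline_duration, x$fps, x$n_trials, x$trial_duration,
              x$arena_diameter))
  cat(sprintf("  thresholds: median %g, log-sd %g, steepness %g, stimulus %g\n",
              x$threshold_mean, x$threshold_sd, x$threshold_steepness,
              x$stimulus))
  cat(sprintf("  activity: log-sd %g, coupling %g, seed %d\n",
              x$activity_sd, x$coupling, x$seed))
  invisible(x)
}

#' Colony design table of a scenario
#'
#' Expands the factorial design of a scenario into one row per colony with a
#' unique colony id, the group size and the brood treatment.
#'
#' @param scenario an `antdol_scenario`.
#' @return A tibble with columns `colony_id`, `group_size`, `brood`.
#' @export
design_table <- function(scenario) {
  validate_scenario(scenario)
  grid <- expand.grid(
    replicate = seq_len(scenario$n_colonies_per_treatment),
    brood = scenario$brood_treatments,
    group_size = scenario$group_sizes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::tibble(
    colony_id = sprintf("C%02d", seq_len(nrow(grid))),
    group_size = as.integer(grid$group_size),
    brood = grid$brood
  )
}
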