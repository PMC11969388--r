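#' Read a behavioural event table from CSV
#'
#' Accepts either the native schema (`colony_id`, `trial`, `ant_id`,
#' `event_type`, `onset`, `offset`) or a minimal annotation-export dialect
#' with `subject`, `behavior` (or `behaviour`), `start`, `stop` columns plus
#' `colony_id` and `trial`; `column_map` renames further dialects. Events
#' with `offset < onset`, negative onsets, or unknown event types are
#' rejected.
#'
#' @param path CSV file.
#' @param column_map optional named character vector mapping native column
#'   names to the file's names, e.g.
#'   `c(ant_id = "subject", event_type = "behavior")`.
#' @param trial_duration if given, offsets beyond it are rejected.
#' @return An event tibble.
#' @export
read_events <- function(path, column_map = NULL, trial_duration = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  boris_map <- c(ant_id = "subject", event_type = "behavior",
                 onset = "start", offset = "stop")
  if (is.null(column_map)) {
    if (!("ant_id" %in% names(raw)) && "subject" %in% names(raw)) {
      column_map <- boris_map
      if (!"behavior" %in% names(raw) && "behaviour" %in% names(raw)) {
        column_map["event_type"] <- "behaviour"
      }
    } else {
      column_map <- character()
    }
  }
  for (native in names(column_map)) {
    src <- column_map[[native]]
    if (!src %in% names(raw)) {
      stop("event file is missing mapped column '", src, "'", call. = FALSE)
    }
    names(raw)[names(raw) == src] <- native
  }
  required <- c("colony_id", "trial", "ant_id", "event_type", "onset",
                "offset")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("event file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ev <- tibble::tibble(
    colony_id = as.character(raw$colony_id),
    trial = as.integer(raw$trial),
    ant_id = as.character(raw$ant_id),
    event_type = tolower(as.character(raw$event_type)),
    onset = as.numeric(raw$onset),
    offset = as.numeric(raw$offset)
  )
  bad_type <- !ev$event_type %in% c("encounter", "sting")
  if (any(bad_type)) {
    stop("unknown event type(s): ",
         paste(unique(ev$event_type[bad_type]), collapse = ", "),
         call. = FALSE)
  }
  if (any(ev$onset < 0) || any(ev$offset < ev$onset)) {
    stop("events must satisfy 0 <= onset <= offset", call. = FALSE)
  }
  if (!is.null(trial_duration) && any(ev$offset > trial_duration)) {
    stop("event offset exceeds trial duration", call. = FALSE)
  }
  ev
}

#' Per-ant defence score
#'
#' `score = (n_stings / n_encounters) * ln(1 + sting_seconds)`: the number
#' of stinging attempts normalised by the number of encounters (capturing
#' the propensity to attack per contact, correcting for encounter-rate
#' variation), weighted by the log of total stinging duration (so long
#' attempts count more without dominating). Ants that never encountered the
#' intruder are assigned a score of 0; ants that never stung score 0 by the
#' formula. Vectorised.
#'
#' @param n_stings number of stinging attempts.
#' @param n_encounters number of encounters with the intruder.
#' @param sting_seconds total duration of stinging attempts, seconds.
#' @return Non-negative scores.
#' @examples
#' defence_score(13, 18, 629.25)  # ~ 4.66
#' defence_score(0, 14, 0)        # 0
#' @export
defence_score <- function(n_stings, n_encounters, sting_seconds) {
  stopifnot(all(n_stings >= 0), all(n_encounters >= 0),
            all(sting_seconds >= 0))
  ifelse(n_encounters == 0, 0,
         n_stings / n_encounters * log1p(sting_seconds))
}

#' Normalised sting rate
#'
#' The simpler defence metric: `n_stings / n_encounters`, 0 when there were
#' no encounters. The ratio may exceed 1 when an ant stings repeatedly
#' within one contact.
#'
#' @inheritParams defence_score
#' @return Non-negative rates.
#' @export
norm_sting_rate <- function(n_stings, n_encounters) {
  stopifnot(all(n_stings >= 0), all(n_encounters >= 0))
  ifelse(n_encounters == 0, 0, n_stings / n_encounters)
}

#' Aggregate events per colony, trial and ant
#'
#' Counts encounters and stinging attempts and sums sting durations for
#' every (colony, trial, ant) cell of the design, including ants (and
#' trials) with no events, which receive `(0, 0, 0)`. Events referring to an
#' ant or colony absent from the roster are a hard error.
#'
#' @param events event tibble (see [read_events()]).
#' @param roster tibble of `colony_id`, `ant_id` listing every ant.
#' @param trials trial indices the design declares (default `1:3`).
#' @return A tibble with `colony_id`, `trial`, `ant_id`, `n_encounters`,
#'   `n_stings`, `sting_seconds`.
#' @export
aggregate_events <- function(events, roster, trials = 1:3) {
  key_r <- paste(roster$colony_id, roster$ant_id, sep = "\r")
  if (nrow(events) > 0) {
    key_e <- paste(events$colony_id, events$ant_id, sep = "\r")
    unknown <- !key_e %in% key_r
    if (any(unknown)) {
      stop("event(s) for ant(s) not in the roster: ",
           paste(unique(events$ant_id[unknown]), collapse = ", "),
           call. = FALSE)
    }
    if (!all(events$trial %in% trials)) {
      stop("event trial index outside declared trials", call. = FALSE)
    }
  }
  grid <- tidyr::crossing(roster, trial = as.integer(trials))
  agg <- events |>
    dplyr::group_by(.data$colony_id, .data$trial, .data$ant_id) |>
    dplyr::summarise(
      n_encounters = sum(.data$event_type == "encounter"),
      n_stings = sum(.data$event_type == "sting"),
      sting_seconds = sum((.data$offset - .data$onset)[
        .data$event_type == "sting"]),
      .groups = "drop"
    )
  grid |>
    dplyr::left_join(agg, by = c("colony_id", "trial", "ant_id")) |>
    dplyr::mutate(
      n_encounters = dplyr::coalesce(.data$n_encounters, 0L),
      n_stings = dplyr::coalesce(.data$n_stings, 0L),
      sting_seconds = dplyr::coalesce(.data$sting_seconds, 0)
    ) |>
    dplyr::arrange(.data$colony_id, .data$trial, .data$ant_id)
}

#' Defence records: per-trial and pooled scores
#'
#' Builds the full defence-record table: per-ant aggregates and scores for
#' each trial, plus a `"pooled"` stratum in which counts and durations are
#' summed across trials first and the score formula applied once to the
#' pooled sums.
#'
#' @inheritParams aggregate_events
#' @return A tibble with `colony_id`, `trial` (`"1"`, `"2"`, ... and
#'   `"pooled"`), `ant_id`, `n_encounters`, `n_stings`, `sting_seconds`,
#'   `score`, `norm_sting_rate`.
#' @export
defence_records <- function(events, roster, trials = 1:3) {
  per_trial <- aggregate_events(events, roster, trials)
  pooled <- per_trial |>
    dplyr::group_by(.data$colony_id, .data$ant_id) |>
    dplyr::summarise(
      n_encounters = sum(.data$n_encounters),
      n_stings = sum(.data$n_stings),
      sting_seconds = sum(.data$sting_seconds),
      .groups = "drop"
    ) |>
    dplyr::mutate(trial = "pooled")
  out <- dplyr::bind_rows(
    dplyr::mutate(per_trial, trial = as.character(.data$trial)),
    pooled
  )
  out |>
    dplyr::mutate(
      score = defence_score(.data$n_stings, .data$n_encounters,
                            .data$sting_seconds),
      norm_sting_rate = norm_sting_rate(.data$n_stings, .data$n_encounters)
    ) |>
    dplyr::select("colony_id", "trial", "ant_id", "n_encounters",
                  "n_stings", "sting_seconds", "score", "norm_sting_rate") |>
    dplyr::arrange(.data$colony_id, .data$trial, .data$ant_id)
}

#' Colony defence efficiency
#'
#' Total number of stinging attempts received by the intruder across all
#' ants and all trials of each colony — the colony-level measure of how
#' effectively the intruder was attacked.
#'
#' @param events event tibble.
#' @param design design tibble (`colony_id`, ...); colonies with no sting
#'   events report 0.
#' @return A tibble of `colony_id`, `total_stings`.
#' @export
colony_efficiency <- function(events, design) {
  stings <- events |>
    dplyr::filter(.data$event_type == "sting") |>
    dplyr::count(.data$colony_id, name = "total_stings")
  design |>
    dplyr::distinct(.data$colony_id) |>
    dplyr::left_join(stings, by = "colony_id") |>
    dplyr::mutate(total_stings = dplyr::coalesce(.data$total_stings, 0L))
}

#' Colony mean defence score
#'
#' Arithmetic mean of member scores (zeros included) per colony and trial
#' stratum, accounting for overall defensive effort. A colony-trial with a
#' missing member record is a hard error, guarded by checking each colony
#' contributes the same number of ants in every stratum.
#'
#' @param records defence-record tibble from [defence_records()].
#' @param roster tibble of `colony_id`, `ant_id`.
#' @return A tibble of `colony_id`, `trial`, `mean_score`, `n_ants`.
#' @export
colony_mean_scores <- function(records, roster) {
  expected <- dplyr::count(roster, .data$colony_id, name = "n_expected")
  out <- records |>
    dplyr::group_by(.data$colony_id, .data$trial) |>
    dplyr::summarise(mean_score = mean(.data$score), n_ants = dplyr::n(),
                     .groups = "drop") |>
    dplyr::left_join(expected, by = "colony_id")
  if (any(is.na(out$n_expected)) || any(out$n_ants != out$n_expected)) {
    stop("missing member record(s) for at least one colony-trial",
         call. = FALSE)
  }
  dplyr::select(out, "colony_id", "trial", "mean_score", "n_ants")
}
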