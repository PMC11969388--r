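#' Read a trajectory table from CSV
#'
#' Expects columns `colony_id`, `ant_id`, `frame`, `x`, `y` (extra columns
#' are dropped). Coordinates that fail to parse as numbers (e.g. `"NA"`,
#' empty fields) are flagged missing, not dropped, so preprocessing can
#' decide their fate. Frames are 0-based; times in seconds are `frame / fps`.
#' An optional `offset` shifts pixel-corner-origin coordinates to the
#' arena-centred frame the metrics assume.
#'
#' @param path CSV file.
#' @param offset numeric length-2 `(dx, dy)` added to every coordinate
#'   (default `c(0, 0)`).
#' @return A trajectory tibble (`colony_id`, `ant_id`, `frame`, `x`, `y`).
#' @export
read_trajectories <- function(path, offset = c(0, 0)) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("colony_id", "ant_id", "frame", "x", "y")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("trajectory file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    colony_id = raw$colony_id,
    ant_id = raw$ant_id,
    frame = as.integer(raw$frame),
    x = suppressWarnings(as.numeric(raw$x)) + offset[1],
    y = suppressWarnings(as.numeric(raw$y)) + offset[2]
  )
  if (anyNA(out$frame)) stop("unparseable frame index", call. = FALSE)
  dup <- duplicated(out[, c("colony_id", "ant_id", "frame")])
  if (any(dup)) {
    stop("duplicated (colony, ant, frame) rows in trajectory file",
         call. = FALSE)
  }
  out
}

#' Write a trajectory table to CSV
#'
#' @param traj trajectory tibble.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess trajectories: flag aberrant positions, interpolate short gaps
#'
#' Applies the tracking-cleanup contract per ant:
#' \enumerate{
#'   \item The frame grid is completed from the ant's first to last observed
#'     frame; absent frames count as missing detections, as do rows with
#'     `NA` coordinates.
#'   \item Positions implying a straight-line speed above `v_max` from the
#'     last accepted position are marked aberrant and treated as missing
#'     (sequential scan, so an isolated jump removes only the jumped frame).
#'   \item Runs of at most `max_gap` consecutive missing frames bounded by
#'     valid positions are filled by linear interpolation; longer runs (and
#'     runs at the edges) are removed.
#' }
#' Every input frame is classified exactly once as kept, interpolated or
#' removed; the per-ant report counts sum to the completed frame count. The
#' operation is idempotent: interpolated segments never exceed `v_max`.
#'
#' @param traj trajectory tibble (see [read_trajectories()]).
#' @param max_gap longest missing run (frames) that is interpolated.
#' @param v_max aberrance speed threshold, mm/s.
#' @param fps frames per second.
#' @return A list with `trajectories` (cleaned tibble with a `status` column,
#'   `"kept"` or `"interpolated"`; removed frames are absent) and `report`
#'   (per-ant tibble of `n_frames`, `n_kept`, `n_interpolated`, `n_removed`,
#'   `n_aberrant`).
#' @export
preprocess_trajectories <- function(traj, max_gap = 10, v_max = 50, fps = 20) {
  stopifnot(max_gap >= 0, v_max > 0, fps > 0)
  required <- c("colony_id", "ant_id", "frame", "x", "y")
  miss <- setdiff(required, names(traj))
  if (length(miss) > 0) {
    stop("trajectory table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pieces <- split(traj, paste(traj$colony_id, traj$ant_id, sep = "\r"))
  clean <- vector("list", length(pieces))
  report <- vector("list", length(pieces))
  for (k in seq_along(pieces)) {
    p <- pieces[[k]][order(pieces[[k]]$frame), ]
    full <- tibble::tibble(
      colony_id = p$colony_id[1],
      ant_id = p$ant_id[1],
      frame = seq(min(p$frame), max(p$frame))
    )
    p <- dplyr::left_join(full, p[, c("frame", "x", "y")], by = "frame")
    missing <- is.na(p$x) | is.na(p$y)
    aberrant <- flag_aberrant_cpp(as.integer(p$frame), p$x, p$y, missing,
                                  fps, v_max)
    gap <- missing | aberrant
    x <- ifelse(gap, NA_real_, p$x)
    y <- ifelse(gap, NA_real_, p$y)
    if (max_gap > 0 && any(gap) && sum(!gap) >= 2) {
      xi <- zoo::na.approx(x, x = p$frame, maxgap = max_gap, na.rm = FALSE)
      yi <- zoo::na.approx(y, x = p$frame, maxgap = max_gap, na.rm = FALSE)
    } else {
      xi <- x
      yi <- y
    }
    status <- dplyr::case_when(
      !gap ~ "kept",
      !is.na(xi) & !is.na(yi) ~ "interpolated",
      TRUE ~ "removed"
    )
    report[[k]] <- tibble::tibble(
      colony_id = p$colony_id[1],
      ant_id = p$ant_id[1],
      n_frames = nrow(p),
      n_kept = sum(status == "kept"),
      n_interpolated = sum(status == "interpolated"),
      n_removed = sum(status == "removed"),
      n_aberrant = sum(aberrant)
    )
    keep <- status != "removed"
    clean[[k]] <- tibble::tibble(
      colony_id = p$colony_id[keep],
      ant_id = p$ant_id[keep],
      frame = p$frame[keep],
      x = xi[keep],
      y = yi[keep],
      status = status[keep]
    )
  }
  list(
    trajectories = dplyr::bind_rows(clean),
    report = dplyr::bind_rows(report)
  )
}
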