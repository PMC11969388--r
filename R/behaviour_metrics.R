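#' Occupancy-grid Shannon entropy of one trajectory
#'
#' The arena bounding square (`arena_diameter` on a side, centred on the
#' dish) is divided into `bins_per_side` x `bins_per_side` cells and each
#' frame is assigned to the cell containing its position. Entropy is
#' `H = -sum p(x) log2 p(x)` over occupied cells, where `p(x)` is the
#' proportion of frames spent in cell `x` (`0 log 0 = 0`). With the default
#' 25 x 25 grid of 2 mm cells, `H` ranges from 0 (all frames in one cell) to
#' `log2(625) ~ 9.288` bits (uniform occupancy). Higher entropy indicates
#' movement spread more evenly over the arena, i.e. more exploratory
#' behaviour.
#'
#' Positions outside the bounding square (not expected after preprocessing)
#' are clamped to the nearest edge cell; their count is available via
#' `attr(, "n_clamped")`.
#'
#' @param x,y coordinates in mm, arena-centred.
#' @param arena_diameter arena (and grid) extent, mm.
#' @param bins_per_side grid resolution per axis.
#' @return Entropy in bits (`NA` if no finite positions), with attribute
#'   `n_clamped`.
#' @examples
#' compute_entropy(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 4 distinct 2 mm cells
#' @export
compute_entropy <- function(x, y, arena_diameter = 50, bins_per_side = 25) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) == 0) {
    return(structure(NA_real_, n_clamped = 0L))
  }
  bin_size <- arena_diameter / bins_per_side
  half <- arena_diameter / 2
  ix <- floor((x + half) / bin_size) + 1
  iy <- floor((y + half) / bin_size) + 1
  n_clamped <- sum(ix < 1 | ix > bins_per_side | iy < 1 | iy > bins_per_side)
  ix <- pmin(pmax(ix, 1), bins_per_side)
  iy <- pmin(pmax(iy, 1), bins_per_side)
  cell <- (iy - 1) * bins_per_side + ix
  counts <- tabulate(cell, nbins = bins_per_side^2)
  p <- counts[counts > 0] / length(x)
  structure(-sum(p * log2(p)), n_clamped = as.integer(n_clamped))
}

#' Baseline activity of one trajectory
#'
#' Per-frame speed is the Euclidean displacement from the previous frame
#' times `fps`; a frame is active when its speed exceeds `speed_threshold`
#' (strictly). Only frames whose immediate predecessor is present are
#' classified; the first frame of each contiguous segment is excluded from
#' the denominator. `prop_active` is the fraction of classified frames that
#' are active; active bouts are maximal runs of consecutive active frames
#' (never spanning a gap) and `mean_bout` is their mean length in seconds
#' (0 when there is no bout).
#'
#' @param frame 0-based frame indices (sorted or not).
#' @param x,y coordinates in mm.
#' @param speed_threshold activity cutoff, mm/s.
#' @param fps frames per second.
#' @return A list with `prop_active`, `mean_bout` (seconds) and
#'   `n_classified`; all `NA`/0 when fewer than 2 consecutive frames exist.
#' @export
compute_activity <- function(frame, x, y, speed_threshold = 1, fps = 20) {
  o <- order(frame)
  frame <- frame[o]
  x <- x[o]
  y <- y[o]
  n <- length(frame)
  if (n < 2) {
    return(list(prop_active = NA_real_, mean_bout = NA_real_,
                n_classified = 0L))
  }
  consec <- c(FALSE, diff(frame) == 1)
  speed <- c(NA_real_, sqrt(diff(x)^2 + diff(y)^2) * fps)
  classified <- consec & !is.na(speed)
  if (!any(classified)) {
    return(list(prop_active = NA_real_, mean_bout = NA_real_,
                n_classified = 0L))
  }
  active <- classified & speed > speed_threshold
  prop_active <- sum(active) / sum(classified)
  runs <- rle(active)
  bouts <- runs$lengths[runs$values]
  mean_bout <- if (length(bouts) == 0) 0 else mean(bouts) / fps
  list(prop_active = prop_active, mean_bout = mean_bout,
       n_classified = sum(classified))
}

#' Per-ant baseline metrics
#'
#' Computes the three baseline behavioural measures for every ant in a
#' (preprocessed) trajectory table: occupancy-grid Shannon entropy
#' ([compute_entropy()]), proportion of time active and mean active-bout
#' duration ([compute_activity()]).
#'
#' @param traj trajectory tibble with `colony_id`, `ant_id`, `frame`, `x`,
#'   `y` (a `status` column, if present, is used to count interpolated
#'   frames in the output).
#' @param arena_diameter,bins_per_side grid specification for entropy.
#' @param speed_threshold,fps activity specification.
#' @return A tibble with one row per ant: `colony_id`, `ant_id`, `H`,
#'   `prop_active`, `mean_bout`, `n_frames`, `n_interpolated`, `n_clamped`.
#' @export
baseline_metrics <- function(traj, arena_diameter = 50, bins_per_side = 25,
                             speed_threshold = 1, fps = 20) {
  has_status <- "status" %in% names(traj)
  key <- paste(traj$colony_id, traj$ant_id, sep = "\r")
  pieces <- split(seq_len(nrow(traj)), key)
  rows <- lapply(pieces, function(i) {
    h <- compute_entropy(traj$x[i], traj$y[i], arena_diameter,
                         bins_per_side)
    act <- compute_activity(traj$frame[i], traj$x[i], traj$y[i],
                            speed_threshold, fps)
    tibble::new_tibble(list(
      colony_id = traj$colony_id[i[1]],
      ant_id = traj$ant_id[i[1]],
      H = as.numeric(h),
      n_clamped = attr(h, "n_clamped"),
      prop_active = act$prop_active,
      mean_bout = act$mean_bout,
      n_frames = length(i),
      n_interpolated = if (has_status) {
        sum(traj$status[i] == "interpolated")
      } else 0L
    ), nrow = 1L)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$colony_id, out$ant_id), ]
}
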