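# Per-frame kinematics, the assay's filtering rules, and the per-run
# behavioral feature set used by the discriminant analysis:
#   distance from screen  — mean head distance over retained gap frames (mm)
#   swim activity         — median frame speed over retained active frames (mm/s)
#   directional bias      — mean of (step toward screen x speed) over the
#                           first seconds of the gap (mm * mm/s)
#   longest trajectory    — direction (+1 toward / -1 away) and duration of
#                           the longest constant-direction movement bout

#' Per-frame kinematic series
#'
#' Computes frame speed, the signed step toward the screen, and yaw (heading
#' change) by forward differences of the head track; the last frame repeats
#' the preceding difference so the series has one row per frame.
#'
#' @param frames A tracking data.frame (>= 2 rows, contiguous in time).
#' @param fps Frame rate, Hz.
#' @return `frames` with added columns `distance` (mm, = `head_x`), `speed`
#'   (mm/s), `toward_step` (mm, positive toward the screen) and `yaw` (rad).
#' @export
compute_series <- function(frames, fps) {
  n <- nrow(frames)
  if (n < 2L) stop("compute_series needs at least 2 frames")
  dx <- diff(frames$head_x)
  dy <- diff(frames$head_y)
  step <- sqrt(dx^2 + dy^2)
  frames$distance <- frames$head_x
  frames$speed <- c(step, step[n - 1L]) * fps
  frames$toward_step <- -c(dx, dx[n - 1L])
  if (all(is.na(frames$heading))) {
    frames$yaw <- NA_real_
  } else {
    dyaw <- diff(frames$heading)
    dyaw <- atan2(sin(dyaw), cos(dyaw))  # wrap to (-pi, pi]
    frames$yaw <- c(dyaw, dyaw[n - 1L])
  }
  frames
}

#' Edge-exclusion filter
#'
#' Discards positions within `screen_margin` of the screen or within
#' `backend_margin` of the back wall, the assay's guard against screen-side
#' lingering and wall-following bias.
#'
#' @param frames A tracking data.frame with `head_x` in canonical mm.
#' @param backend_margin,screen_margin Margins in mm.
#' @param tank A [tank_geometry()].
#' @return The retained subset.
#' @export
filter_edges <- function(frames, backend_margin = 10, screen_margin = 20,
                         tank = tank_geometry()) {
  stopifnot(backend_margin >= 0, screen_margin >= 0,
            backend_margin + screen_margin < tank$length)
  frames[frames$head_x >= screen_margin &
           frames$head_x <= tank$length - backend_margin, , drop = FALSE]
}

#' Swim-activity filter
#'
#' Retains frames whose speed exceeds the activity threshold; successive
#' slower frames are discarded when estimating active swim locations.
#'
#' @param series A data.frame with a `speed` column (see [compute_series()]).
#' @param threshold Speed threshold, mm/s.
#' @return The retained subset.
#' @export
filter_activity <- function(series, threshold = 16) {
  stopifnot(threshold >= 0)
  series[series$speed > threshold, , drop = FALSE]
}

#' Directional bias over the early gap
#'
#' Mean over the window frames of `toward_step * speed`: the signed product
#' of the per-frame displacement toward the screen (mm) and the frame speed
#' (mm/s). Positive values indicate net approach.
#'
#' @param series Gap-epoch rows of a [compute_series()] result, in time
#'   order.
#' @param fps Frame rate, Hz.
#' @param window Averaging window from gap onset, seconds.
#' @return The signed bias (mm * mm/s), or `NA` if the window is empty.
#' @export
directional_bias <- function(series, fps, window = 2) {
  k <- min(nrow(series), round(window * fps))
  if (k < 1L) return(NA_real_)
  s <- series[seq_len(k), ]
  mean(s$toward_step * s$speed)
}

#' Longest constant-direction trajectory in a gap
#'
#' Segments the gap into maximal bouts of consecutive frames moving in a
#' constant direction along the screen axis (sign of `toward_step`) at speed
#' above `min_speed`, tolerating isolated single-frame sign flips, and
#' returns the longest bout (ties go to the earlier one).
#'
#' @param series Gap-epoch rows of a [compute_series()] result.
#' @param fps Frame rate, Hz.
#' @param min_speed Minimum frame speed, mm/s.
#' @return A list with `direction` (+1 toward screen, -1 away, `NA` if no
#'   active frames), `duration` (s) and `n_frames`.
#' @export
longest_trajectory <- function(series, fps, min_speed = 0) {
  if (nrow(series) < 2L) stop("longest_trajectory needs >= 2 gap frames")
  active <- series$speed > min_speed & series$toward_step != 0
  if (!any(active)) return(list(direction = NA_real_, duration = NA_real_,
                                n_frames = 0L))
  s <- sign(series$toward_step)
  n <- length(s)
  # absorb isolated single-frame sign flips (verbal definition smoothing)
  if (n >= 3L) {
    flip <- which(s[2:(n - 1L)] != s[1:(n - 2L)] & s[1:(n - 2L)] == s[3:n]) + 1L
    s[flip] <- s[flip - 1L]
  }
  key <- ifelse(active, s, 0)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values != 0
  if (!any(ok)) return(list(direction = NA_real_, duration = NA_real_,
                            n_frames = 0L))
  lens <- r$lengths[ok]
  best <- which.max(lens)   # which.max takes the earliest tie
  list(direction = r$values[ok][best],
       duration = lens[best] / fps,
       n_frames = as.integer(lens[best]))
}

#' Extract the per-run (or per-frame) behavioral feature table
#'
#' For each conditioning run, takes the gap-interval frames, applies the
#' edge-exclusion filter, and computes the assay's response parameters.
#' `pooling = "run"` gives one row per (fish, run) — the independent-sample
#' mode used for cohort-level inference. `pooling = "frame"` gives one row
#' per retained gap frame (after edge, optional decision-zone and activity
#' filtering) — the descriptive frame-pooled mode; frame-level rows are not
#' independent samples.
#'
#' @param session A `simulated_session`, or a tracking data.frame already
#'   annotated by [segment_frames()].
#' @param config An [experiment_config()].
#' @param pooling `"run"` or `"frame"`.
#' @param runs Run indices to include (default: all conditioned runs).
#' @param zone Optional `c(lower, upper)` mm decision-zone restriction
#'   (frame mode).
#' @param activity_filter Apply the swim-activity threshold in frame mode?
#' @return A data.frame; run mode columns are `fish_id`, `run_index`,
#'   `block_id`, `cue`, `distance_from_screen`, `swim_activity`,
#'   `directional_bias`, `longest_traj_direction`, `longest_traj_duration`,
#'   `n_gap_frames`; frame mode columns are `fish_id`, `run_index`, `cue`,
#'   `distance`, `activity`, `bias`.
#' @export
extract_features <- function(session, config = experiment_config(),
                             pooling = c("run", "frame"), runs = NULL,
                             zone = NULL, activity_filter = TRUE) {
  pooling <- match.arg(pooling)
  frames <- if (inherits(session, "simulated_session")) session$frames else session
  stopifnot(all(c("epoch_kind", "run_index", "cue") %in% names(frames)))
  if (!"speed" %in% names(frames))
    frames <- compute_series(frames, config$fps)
  gap <- frames[frames$epoch_kind == "gap", , drop = FALSE]
  if (!is.null(runs)) gap <- gap[gap$run_index %in% runs, , drop = FALSE]

  if (pooling == "frame") {
    g <- filter_edges(gap, config$backend_margin, config$screen_margin,
                      config$tank)
    if (!is.null(zone))
      g <- g[g$distance >= zone[1] & g$distance <= zone[2], , drop = FALSE]
    if (activity_filter) g <- filter_activity(g, config$activity_threshold)
    out <- data.frame(fish_id = g$fish_id, run_index = g$run_index,
                      cue = g$cue, distance = g$distance,
                      activity = g$speed,
                      bias = g$toward_step * g$speed)
    rownames(out) <- NULL
    return(out)
  }

  run_ids <- sort(unique(gap$run_index))
  rows <- lapply(run_ids, function(r) {
    g <- gap[gap$run_index == r, , drop = FALSE]
    ge <- filter_edges(g, config$backend_margin, config$screen_margin,
                       config$tank)
    ga <- filter_activity(ge, config$activity_threshold)
    bias_sub <- ge[ge$time < g$time[1] + config$bias_window, , drop = FALSE]
    lt <- if (nrow(g) >= 2L)
      longest_trajectory(g, config$fps, config$min_traj_speed)
    else list(direction = NA_real_, duration = NA_real_, n_frames = 0L)
    data.frame(
      fish_id = g$fish_id[1], run_index = r, block_id = g$block_id[1],
      cue = g$cue[1],
      distance_from_screen = if (nrow(ge)) mean(ge$distance) else NA_real_,
      swim_activity = if (nrow(ga)) stats::median(ga$speed) else NA_real_,
      directional_bias = if (nrow(bias_sub))
        mean(bias_sub$toward_step * bias_sub$speed) else NA_real_,
      longest_traj_direction = lt$direction,
      longest_traj_duration = lt$duration,
      n_gap_frames = nrow(g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract features for a whole cohort
#'
#' @param sessions A list of `simulated_session` objects (or annotated
#'   tracking data.frames).
#' @inheritParams extract_features
#' @return The row-bound feature table across fish.
#' @export
extract_features_cohort <- function(sessions, config = experiment_config(),
                                    pooling = c("run", "frame"), runs = NULL,
                                    zone = NULL, activity_filter = TRUE) {
  pooling <- match.arg(pooling)
  do.call(rbind, lapply(sessions, extract_features, config = config,
                        pooling = pooling, runs = runs, zone = zone,
                        activity_filter = activity_filter))
}
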