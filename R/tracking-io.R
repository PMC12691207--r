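# Experiment configuration, trial timeline, and tracking-table I/O.
#
# Canonical coordinate frame: head_x is the distance from the screen plane
# (0 at the screen, increasing toward the back of the tank, mm); head_y runs
# across the tank width. Tracker exports in pixels are converted on read.

#' Tank geometry
#'
#' @param length Tank length along the screen axis, mm.
#' @param width Tank width, mm.
#' @return An object of class `tank_geometry`.
#' @export
tank_geometry <- function(length = 250, width = 130) {
  stopifnot(length > 0, width > 0)
  structure(list(length = length, width = width), class = "tank_geometry")
}

#' Experiment configuration
#'
#' Collects the assay's structural constants: frame rate, tank geometry,
#' pixel calibration, the three-block trial design (six runs per block;
#' Block 3 interleaves three rewarded NCF and three aversive DFM runs in
#' randomized order), epoch durations, the edge-exclusion margins, the swim
#' activity threshold and the directional-bias window.
#'
#' @param fps Video frame rate, Hz.
#' @param tank A [tank_geometry()].
#' @param mm_per_px Pixel calibration (mm per pixel) for pixel-frame tables.
#' @param pixels Are tracking tables in pixels (`TRUE`) or canonical mm?
#' @param screen_x_px Pixel x-coordinate of the screen plane.
#' @param screen_side `"low"` if the screen sits at low pixel x, `"high"` if
#'   at high pixel x (distance then increases with decreasing pixel x).
#' @param runs_per_block,n_blocks Trial-block design (default 6 x 3 = 18 runs).
#' @param run_baseline_duration,cs_duration,gap_duration,us_duration Epoch
#'   durations in seconds (10 s pre-cue baseline, 6 s sound, 3 s silent gap,
#'   then the video unconditioned stimulus).
#' @param iti_range Inter-trial interval range, seconds (drawn uniformly).
#' @param session_baseline_duration Free-swim baseline before and after the
#'   session, seconds (6 min).
#' @param backend_margin,screen_margin Edge-exclusion margins, mm (positions
#'   within 10 mm of the back wall or 20 mm of the screen are discarded).
#' @param density_screen_margin Wider screen-side margin used for positional
#'   density plots, mm.
#' @param activity_threshold Swim-activity cutoff, mm/s (frames slower than
#'   this are discarded for the activity metric).
#' @param bias_window Directional-bias averaging window at gap onset, s.
#' @param min_traj_speed Minimum frame speed for longest-trajectory
#'   segmentation, mm/s.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(fps = 10,
                              tank = tank_geometry(),
                              mm_per_px = 1,
                              pixels = FALSE,
                              screen_x_px = 0,
                              screen_side = c("low", "high"),
                              runs_per_block = 6L,
                              n_blocks = 3L,
                              run_baseline_duration = 10,
                              cs_duration = 6,
                              gap_duration = 3,
                              us_duration = 10,
                              iti_range = c(100, 200),
                              session_baseline_duration = 360,
                              backend_margin = 10,
                              screen_margin = 20,
                              density_screen_margin = 40,
                              activity_threshold = 16,
                              bias_window = 2,
                              min_traj_speed = 0) {
  screen_side <- match.arg(screen_side)
  stopifnot(fps > 0, inherits(tank, "tank_geometry"), mm_per_px > 0,
            runs_per_block >= 1, n_blocks >= 1,
            length(iti_range) == 2L, iti_range[1] <= iti_range[2],
            backend_margin >= 0, screen_margin >= 0,
            backend_margin + screen_margin < tank$length,
            activity_threshold >= 0, bias_window > 0)
  structure(list(fps = fps, tank = tank, mm_per_px = mm_per_px,
                 pixels = pixels, screen_x_px = screen_x_px,
                 screen_side = screen_side,
                 runs_per_block = as.integer(runs_per_block),
                 n_blocks = as.integer(n_blocks),
                 run_baseline_duration = run_baseline_duration,
                 cs_duration = cs_duration, gap_duration = gap_duration,
                 us_duration = us_duration, iti_range = iti_range,
                 session_baseline_duration = session_baseline_duration,
                 backend_margin = backend_margin,
                 screen_margin = screen_margin,
                 density_screen_margin = density_screen_margin,
                 activity_threshold = activity_threshold,
                 bias_window = bias_window,
                 min_traj_speed = min_traj_speed),
            class = "experiment_config")
}

#' Build a session timeline
#'
#' Lays out the epochs of one conditioning session: a 6 min pre-session
#' baseline; then each run as 10 s baseline, 6 s conditioned sound (CS),
#' 3 s silent gap, the video unconditioned stimulus (US), and a randomized
#' 100--200 s inter-trial interval; then a 6 min post-session baseline.
#' Blocks 1 and 2 each present one cue throughout (which cue comes first is
#' randomized); Block 3 interleaves three rewarded NCF and three aversive
#' DFM runs in randomized order.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed controlling block order, Block-3 interleaving and
#'   the ITI draws.
#' @param cue_sequence Optional explicit character vector (`"NCF"`/`"DFM"`,
#'   one per run) overriding the block design.
#' @param n_blocks Optional override of `config$n_blocks` (e.g. a contracted
#'   single-block day-2 session).
#' @return A data.frame of class `session_timeline` with columns
#'   `run_index` (0 for session baselines), `block_id`, `cue`
#'   (`"NCF"`, `"DFM"` or `"none"`), `epoch_kind`
#'   (`baseline`/`cs`/`gap`/`us`/`iti`), `start`, `end` (seconds). Epochs are
#'   contiguous, non-overlapping, half-open `[start, end)`.
#' @export
build_timeline <- function(config = experiment_config(), seed = 1L,
                           cue_sequence = NULL, n_blocks = NULL) {
  if (is.null(n_blocks)) n_blocks <- config$n_blocks
  rpb <- config$runs_per_block
  n_runs <- n_blocks * rpb
  with_local_seed(seed, {
    if (is.null(cue_sequence)) {
      first <- sample(c("NCF", "DFM"), 1L)
      other <- setdiff(c("NCF", "DFM"), first)
      cue_sequence <- character(0)
      for (b in seq_len(n_blocks)) {
        cues <- if (b == 1L) rep(first, rpb)
        else if (b == 2L) rep(other, rpb)
        else sample(rep(c("NCF", "DFM"), length.out = rpb))
        cue_sequence <- c(cue_sequence, cues)
      }
    }
    stopifnot(length(cue_sequence) == n_runs,
              all(cue_sequence %in% c("NCF", "DFM")))
    itis <- stats::runif(n_runs, config$iti_range[1], config$iti_range[2])
    rows <- list()
    t0 <- 0
    add <- function(run, block, cue, kind, dur) {
      rows[[length(rows) + 1L]] <<- data.frame(
        run_index = run, block_id = block, cue = cue, epoch_kind = kind,
        start = t0, end = t0 + dur)
      t0 <<- t0 + dur
    }
    add(0L, NA_integer_, "none", "baseline", config$session_baseline_duration)
    for (r in seq_len(n_runs)) {
      b <- ((r - 1L) %/% rpb) + 1L
      cue <- cue_sequence[r]
      add(r, b, "none", "baseline", config$run_baseline_duration)
      add(r, b, cue, "cs", config$cs_duration)
      add(r, b, cue, "gap", config$gap_duration)
      add(r, b, cue, "us", config$us_duration)
      add(r, b, "none", "iti", itis[r])
    }
    add(0L, NA_integer_, "none", "baseline", config$session_baseline_duration)
    tl <- do.call(rbind, rows)
    class(tl) <- c("session_timeline", "data.frame")
    tl
  })
}

#' @export
print.session_timeline <- function(x, ...) {
  n_runs <- max(x$run_index)
  cat(sprintf("<session_timeline: %d runs, %d epochs, %.1f s total>\n",
              n_runs, nrow(x), max(x$end)))
  invisible(x)
}

# header aliases for common tracker export dialects (lowercased, stripped of
# non-alphanumerics)
.tracking_aliases <- list(
  fish_id = c("fishid", "fish", "animalid", "id"),
  frame_index = c("frameindex", "frame", "framenumber", "boutstart"),
  time = c("time", "times", "timestamp"),
  head_x = c("headx", "xhead", "headposx", "x", "posx"),
  head_y = c("heady", "yhead", "headposy", "y", "posy"),
  tail_x = c("tailx", "xtail", "tailposx", "tailx1"),
  tail_y = c("taily", "ytail", "tailposy", "taily1"),
  heading = c("heading", "bodyangle", "angle", "headingdirection")
)

resolve_tracking_columns <- function(nms) {
  norm <- tolower(gsub("[^a-z0-9]", "", tolower(nms)))
  out <- vapply(names(.tracking_aliases), function(canon) {
    hit <- which(norm %in% .tracking_aliases[[canon]])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  out
}

#' Read a per-frame tracking table
#'
#' Reads a CSV tracking export (header aliases for common tracker dialects
#' are recognized), converts pixel coordinates to the canonical mm frame
#' (screen plane at distance 0) using the config calibration, and sorts rows
#' by frame index. Gaps in the frame index are tolerated and flagged in the
#' `"frame_gaps"` attribute. Extra columns are preserved.
#'
#' @param path CSV file path.
#' @param config An [experiment_config()] providing fps and calibration.
#' @return A data.frame of class `tracking_frames` with canonical columns
#'   `fish_id`, `frame_index`, `time`, `head_x`, `head_y`, `tail_x`,
#'   `tail_y`, `heading`.
#' @export
read_tracking <- function(path, config = experiment_config()) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty tracking table: ", path)
    return(empty_tracking())
  }
  idx <- resolve_tracking_columns(names(raw))
  needed <- c("frame_index", "head_x", "head_y")
  missing <- needed[is.na(idx[needed])]
  if (length(missing))
    stop("tracking format error: missing mandatory columns ",
         paste(missing, collapse = ", "))
  out <- data.frame(
    fish_id = if (!is.na(idx["fish_id"])) raw[[idx["fish_id"]]] else "fish1",
    frame_index = as.integer(raw[[idx["frame_index"]]]),
    head_x = as.numeric(raw[[idx["head_x"]]]),
    head_y = as.numeric(raw[[idx["head_y"]]]),
    tail_x = if (!is.na(idx["tail_x"])) as.numeric(raw[[idx["tail_x"]]]) else NA_real_,
    tail_y = if (!is.na(idx["tail_y"])) as.numeric(raw[[idx["tail_y"]]]) else NA_real_,
    heading = if (!is.na(idx["heading"])) as.numeric(raw[[idx["heading"]]]) else NA_real_
  )
  out$time <- if (!is.na(idx["time"])) as.numeric(raw[[idx["time"]]])
  else out$frame_index / config$fps
  out <- out[order(out$frame_index), ]
  if (is.unsorted(out$time)) stop("tracking format error: non-monotone time")
  if (config$pixels) {
    to_mm_x <- function(px) {
      if (config$screen_side == "high") config$mm_per_px * (config$screen_x_px - px)
      else config$mm_per_px * (px - config$screen_x_px)
    }
    out$head_x <- to_mm_x(out$head_x)
    out$tail_x <- to_mm_x(out$tail_x)
    out$head_y <- out$head_y * config$mm_per_px
    out$tail_y <- out$tail_y * config$mm_per_px
    if (config$screen_side == "high" && !all(is.na(out$heading)))
      out$heading <- pi - out$heading   # mirror the x axis
  }
  extra <- raw[, setdiff(seq_along(raw), stats::na.omit(idx)), drop = FALSE]
  if (ncol(extra)) out <- cbind(out, extra[order(raw[[idx["frame_index"]]]), , drop = FALSE])
  out <- out[, c("fish_id", "frame_index", "time", "head_x", "head_y",
                 "tail_x", "tail_y", "heading",
                 setdiff(names(out), c("fish_id", "frame_index", "time",
                                       "head_x", "head_y", "tail_x", "tail_y",
                                       "heading")))]
  rownames(out) <- NULL
  d <- diff(out$frame_index)
  gaps <- which(d > 1L)
  if (length(gaps)) attr(out, "frame_gaps") <- out$frame_index[gaps]
  class(out) <- c("tracking_frames", "data.frame")
  out
}

empty_tracking <- function() {
  out <- data.frame(fish_id = character(0), frame_index = integer(0),
                    time = numeric(0), head_x = numeric(0), head_y = numeric(0),
                    tail_x = numeric(0), tail_y = numeric(0),
                    heading = numeric(0))
  class(out) <- c("tracking_frames", "data.frame")
  out
}

#' Write a tracking table to CSV (canonical mm schema)
#'
#' @param frames A tracking data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(frames, path) {
  cols <- c("fish_id", "frame_index", "time", "head_x", "head_y",
            "tail_x", "tail_y", "heading")
  stopifnot(all(cols %in% names(frames)))
  utils::write.csv(as.data.frame(frames)[, union(cols, names(frames))],
                   path, row.names = FALSE)
  invisible(path)
}

#' Assign frames to timeline epochs
#'
#' Annotates each frame with the epoch it falls in (half-open
#' `[start, end)` intervals: a frame exactly on a boundary belongs to the
#' later epoch). Frames outside the timeline span are assigned to the
#' nearest session baseline and flagged in the `out_of_span` column.
#'
#' @param frames A tracking data.frame with a `time` column sharing the
#'   timeline's clock.
#' @param timeline A [build_timeline()] result.
#' @return The frames with added columns `run_index`, `block_id`, `cue`,
#'   `epoch_kind` and logical `out_of_span`.
#' @export
segment_frames <- function(frames, timeline) {
  stopifnot("time" %in% names(frames))
  idx <- findInterval(frames$time, timeline$start)
  oos <- idx < 1L | frames$time >= max(timeline$end)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(timeline)] <- nrow(timeline)
  frames$run_index <- timeline$run_index[idx]
  frames$block_id <- timeline$block_id[idx]
  frames$cue <- timeline$cue[idx]
  frames$epoch_kind <- timeline$epoch_kind[idx]
  frames$out_of_span <- oos
  if (any(oos))
    warning(sum(oos), " frame(s) outside the timeline span; assigned to the nearest baseline")
  frames
}

#' Pixel calibration helpers
#'
#' Convert between pixel x-coordinates and canonical distance-from-screen mm.
#'
#' @param px,mm Coordinates to convert.
#' @param config An [experiment_config()].
#' @return Converted coordinates.
#' @export
px_to_mm <- function(px, config) {
  if (config$screen_side == "high") config$mm_per_px * (config$screen_x_px - px)
  else config$mm_per_px * (px - config$screen_x_px)
}

#' @rdname px_to_mm
#' @export
mm_to_px <- function(mm, config) {
  if (config$screen_side == "high") config$screen_x_px - mm / config$mm_per_px
  else config$screen_x_px + mm / config$mm_per_px
}
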