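# Agent-based swim simulator: correlated random walk with cue-conditioned
# approach/avoidance drift, run-wise saturating learning, sinusoidal
# attention modulation, per-run decay of turning noise, post-aversive
# hysteresis at gap onset, and reflecting walls with an inward bias near
# the tank edges. The pipeline's testbed in place of real tracking data.

#' Fish behavioral policy
#'
#' Parameters of the simulated fish. The cue-conditioned drift in run `r`
#' is `gain_max * (1 - exp(-r / learning_tau)) * attention_r` mm/s along the
#' screen axis (toward the screen under NCF, away under DFM), applied during
#' the CS and gap epochs. `attention_r = 1 - attention_amplitude *
#' (1 + sin(2*pi*r/attention_period)) / 2` waxes and wanes across runs.
#' Turning noise decays across runs: `sigma_r = noise_sigma0 *
#' noise_decay^r`. If the preceding run was aversive, the first
#' `hysteresis_frames` frames of the gap carry an extra away-from-screen
#' drift (lingering avoidance).
#'
#' @param base_speed_mean Mean frame speed, mm/s (lognormal; 0 = stationary).
#' @param base_speed_cv Coefficient of variation of frame speed.
#' @param heading_persistence AR(1) coefficient of the turning increments,
#'   in `[0, 1)`.
#' @param noise_sigma0 Initial turning-noise SD, rad/frame.
#' @param noise_decay Per-run multiplicative decay of turning noise (<= 1).
#' @param approach_gain_max Asymptotic approach drift under NCF, mm/s.
#' @param avoid_gain_max Asymptotic avoidance drift under DFM, mm/s.
#' @param learning_tau Learning time constant, runs.
#' @param attention_amplitude Depth of attention modulation, `[0, 1]`.
#' @param attention_period Attention oscillation period, runs.
#' @param hysteresis_frames Frames of post-aversive away-drift at gap onset.
#' @param wall_margin Wall-following zone depth, mm.
#' @param wall_bias Inward bias at full margin depth, mm/s.
#' @param warm_start_runs Run-index offset for the learning and noise
#'   schedules (used for day-2 sessions that resume learned gains).
#' @param tonic_anticipation Fraction (in `[0, 1]`) of the learned gain
#'   applied as a tonic goal-ward drift outside the CS/gap epochs of
#'   single-cue (retraining) sessions — anticipatory station-keeping near
#'   the learned goal after consolidation. 0 for naive fish.
#' @param seed Default seed used by [simulate_session()] when none is given.
#' @return An object of class `fish_policy`.
#' @export
fish_policy <- function(base_speed_mean = 25,
                        base_speed_cv = 0.6,
                        heading_persistence = 0.5,
                        noise_sigma0 = 0.8,
                        noise_decay = 0.97,
                        approach_gain_max = 9,
                        avoid_gain_max = 9,
                        learning_tau = 3,
                        attention_amplitude = 0.3,
                        attention_period = 6,
                        hysteresis_frames = 10L,
                        wall_margin = 15,
                        wall_bias = 10,
                        warm_start_runs = 0,
                        tonic_anticipation = 0,
                        seed = NULL) {
  stopifnot(base_speed_mean >= 0, base_speed_cv >= 0,
            heading_persistence >= 0, heading_persistence < 1,
            noise_sigma0 >= 0, noise_decay > 0, noise_decay <= 1,
            approach_gain_max >= 0, avoid_gain_max >= 0, learning_tau > 0,
            attention_amplitude >= 0, attention_amplitude <= 1,
            attention_period > 0, hysteresis_frames >= 0,
            wall_margin >= 0, warm_start_runs >= 0,
            tonic_anticipation >= 0, tonic_anticipation <= 1)
  structure(list(base_speed_mean = base_speed_mean,
                 base_speed_cv = base_speed_cv,
                 heading_persistence = heading_persistence,
                 noise_sigma0 = noise_sigma0, noise_decay = noise_decay,
                 approach_gain_max = approach_gain_max,
                 avoid_gain_max = avoid_gain_max,
                 learning_tau = learning_tau,
                 attention_amplitude = attention_amplitude,
                 attention_period = attention_period,
                 hysteresis_frames = as.integer(hysteresis_frames),
                 wall_margin = wall_margin, wall_bias = wall_bias,
                 warm_start_runs = warm_start_runs,
                 tonic_anticipation = tonic_anticipation, seed = seed),
            class = "fish_policy")
}

#' @export
print.fish_policy <- function(x, ...) {
  cat(sprintf(paste0("<fish_policy: speed %g mm/s (cv %g), sigma0 %g rad ",
                     "(decay %g/run), gains %g/%g mm/s (tau %g runs)>\n"),
              x$base_speed_mean, x$base_speed_cv, x$noise_sigma0,
              x$noise_decay, x$approach_gain_max, x$avoid_gain_max,
              x$learning_tau))
  invisible(x)
}

attention_at <- function(policy, run) {
  1 - policy$attention_amplitude *
    (1 + sin(2 * pi * run / policy$attention_period)) / 2
}

learned_gain <- function(gain_max, run, tau) {
  ifelse(run >= 1, gain_max * (1 - exp(-run / tau)), 0)
}

#' Simulate one tracked session
#'
#' Runs the correlated-random-walk simulator over a full session timeline at
#' fixed frame rate and returns per-frame head/tail/heading samples in the
#' canonical mm frame, annotated with their timeline epoch. Deterministic
#' given the seed.
#'
#' @param policy A [fish_policy()].
#' @param timeline A [build_timeline()] result.
#' @param geometry A [tank_geometry()].
#' @param fps Frame rate, Hz.
#' @param seed Integer seed (falls back to `policy$seed`).
#' @param fish_id Identifier stored in the frames.
#' @return An object of class `simulated_session`: a list with `fish_id`,
#'   `policy`, `timeline` and `frames` (a `tracking_frames` data.frame with
#'   epoch annotations).
#' @export
simulate_session <- function(policy, timeline, geometry = tank_geometry(),
                             fps = 10, seed = NULL, fish_id = "fish1") {
  stopifnot(inherits(policy, "fish_policy"), fps > 0)
  if (is.null(seed)) seed <- policy$seed
  total <- max(timeline$end)
  n <- as.integer(round(total * fps))
  time <- (seq_len(n) - 1L) / fps
  idx <- findInterval(time, timeline$start)
  idx[idx < 1L] <- 1L
  run <- timeline$run_index[idx]
  kind <- timeline$epoch_kind[idx]
  cue <- timeline$cue[idx]
  w <- policy$warm_start_runs
  eff_run <- run + w

  att <- attention_at(policy, eff_run)
  drift <- numeric(n)
  in_cue <- kind %in% c("cs", "gap") & cue != "none"
  g_app <- learned_gain(policy$approach_gain_max, eff_run, policy$learning_tau)
  g_avo <- learned_gain(policy$avoid_gain_max, eff_run, policy$learning_tau)
  drift[in_cue & cue == "NCF"] <- (-g_app * att)[in_cue & cue == "NCF"]
  drift[in_cue & cue == "DFM"] <- (+g_avo * att)[in_cue & cue == "DFM"]

  # anticipatory station-keeping near the learned goal (consolidated,
  # single-cue retraining sessions only): tonic goal-ward drift outside the
  # cue epochs, a fraction of the learned gain
  session_cues <- unique(cue[cue != "none"])
  if (policy$tonic_anticipation > 0 && length(session_cues) == 1L) {
    s_dir <- if (session_cues == "NCF") -1 else +1
    g_max <- if (session_cues == "NCF") policy$approach_gain_max
    else policy$avoid_gain_max
    tonic <- policy$tonic_anticipation *
      learned_gain(g_max, pmax(eff_run, w), policy$learning_tau)
    drift[!in_cue] <- (s_dir * tonic)[!in_cue]
  }

  # post-aversive hysteresis: lingering away-drift at gap onset
  if (policy$hysteresis_frames > 0) {
    runs <- unique(run[run >= 1L])
    run_cue <- vapply(runs, function(r) cue[match(r, run)], character(1))
    for (r in runs) {
      prev <- match(r - 1L, runs)
      if (!is.na(prev) && run_cue[prev] == "DFM") {
        gi <- which(run == r & kind == "gap")
        gi <- gi[seq_len(min(policy$hysteresis_frames, length(gi)))]
        drift[gi] <- drift[gi] +
          learned_gain(policy$avoid_gain_max, r - 1L + w, policy$learning_tau) *
          attention_at(policy, r - 1L + w)
      }
    }
  }

  sigma <- policy$noise_sigma0 * policy$noise_decay^eff_run
  if (policy$base_speed_cv > 0) {
    sdlog <- sqrt(log(1 + policy$base_speed_cv^2))
  } else sdlog <- 0
  zero_speed <- policy$base_speed_mean <= 0
  meanlog <- if (zero_speed) -Inf else log(policy$base_speed_mean) - sdlog^2 / 2

  with_local_seed(seed, {
    theta0 <- stats::runif(1, -pi, pi)
    sim <- simulate_frames_cpp(n, 1 / fps, drift, sigma,
                               meanlog, sdlog, zero_speed,
                               policy$heading_persistence,
                               policy$wall_margin, policy$wall_bias,
                               geometry$length, geometry$width,
                               geometry$length / 2, geometry$width / 2, theta0)
    body_len <- 10
    tail_x <- pmin(pmax(sim$x - body_len * cos(sim$heading), 0), geometry$length)
    tail_y <- pmin(pmax(sim$y - body_len * sin(sim$heading), 0), geometry$width)
    frames <- data.frame(fish_id = fish_id, frame_index = seq_len(n) - 1L,
                         time = time, head_x = sim$x, head_y = sim$y,
                         tail_x = tail_x, tail_y = tail_y,
                         heading = sim$heading,
                         run_index = run, block_id = timeline$block_id[idx],
                         cue = cue, epoch_kind = kind, out_of_span = FALSE)
    class(frames) <- c("tracking_frames", "data.frame")
    structure(list(fish_id = fish_id, policy = policy, timeline = timeline,
                   frames = frames),
              class = "simulated_session")
  })
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("<simulated_session %s: %d frames, %d runs>\n", x$fish_id,
              nrow(x$frames), max(x$timeline$run_index)))
  invisible(x)
}

#' Default inter-individual policy sampler
#'
#' Returns a sampler that jitters speed, turning noise and drift gains
#' lognormally around a base policy (inter-individual variability).
#'
#' @param base A [fish_policy()].
#' @param speed_sd,gain_sd,sigma_sd Lognormal SDs of the jitters.
#' @return A function `(seed) -> fish_policy`.
#' @export
policy_sampler <- function(base = fish_policy(), speed_sd = 0.15,
                           gain_sd = 0.2, sigma_sd = 0.1) {
  force(base)
  function(seed) {
    with_local_seed(seed, {
      p <- base
      p$base_speed_mean <- base$base_speed_mean * exp(stats::rnorm(1, 0, speed_sd))
      p$approach_gain_max <- base$approach_gain_max * exp(stats::rnorm(1, 0, gain_sd))
      p$avoid_gain_max <- base$avoid_gain_max * exp(stats::rnorm(1, 0, gain_sd))
      p$noise_sigma0 <- base$noise_sigma0 * exp(stats::rnorm(1, 0, sigma_sd))
      p
    })
  }
}

#' Simulate a cohort of fish
#'
#' Simulates `n_fish` independent sessions. Per-fish seeds are derived from
#' the master seed; each fish gets its own policy draw (inter-individual
#' variability) and its own timeline randomization (block order, Block-3
#' interleaving, ITIs) unless a fixed timeline is supplied.
#'
#' @param n_fish Number of fish.
#' @param config An [experiment_config()].
#' @param sampler A policy sampler as returned by [policy_sampler()], or a
#'   `fish_policy` used for every fish.
#' @param seed Master integer seed.
#' @param timeline Optional fixed [build_timeline()] shared by all fish.
#' @param n_blocks Optional block-count override passed to [build_timeline()].
#' @return A list of `simulated_session` objects.
#' @export
simulate_cohort <- function(n_fish, config = experiment_config(),
                            sampler = policy_sampler(), seed = 1L,
                            timeline = NULL, n_blocks = NULL) {
  stopifnot(n_fish >= 1)
  if (inherits(sampler, "fish_policy")) {
    base <- sampler
    sampler <- function(seed) base
  }
  fish_seeds <- with_local_seed(seed,
                                sample.int(.Machine$integer.max, 2L * n_fish))
  lapply(seq_len(n_fish), function(i) {
    tl <- if (is.null(timeline))
      build_timeline(config, seed = fish_seeds[2L * i - 1L], n_blocks = n_blocks)
    else timeline
    pol <- sampler(fish_seeds[2L * i - 1L])
    simulate_session(pol, tl, config$tank, fps = config$fps,
                     seed = fish_seeds[2L * i],
                     fish_id = sprintf("fish%02d", i))
  })
}

#' Derive a day-2 (post-consolidation) policy
#'
#' Overnight consolidation is modelled as a contraction of behavioral noise
#' with retention of the learned drift gains: turning noise is multiplied by
#' `consolidation_factor`, the learning/noise schedules are warm-started at
#' their day-1 terminal run index, and the fish acquires anticipatory
#' station-keeping — a tonic goal-ward drift of `(1 - consolidation_factor)`
#' times the learned gain outside the cue epochs of single-cue retraining
#' sessions (consolidated fish start trials closer to their learned goal).
#'
#' @param policy The day-1 [fish_policy()].
#' @param consolidation_factor In `[0, 1]`; 1 leaves the policy unchanged.
#' @param day1_runs Number of day-1 runs the learning curve has consumed.
#' @return A `fish_policy`.
#' @export
day2_policy <- function(policy, consolidation_factor, day1_runs = 18L) {
  stopifnot(consolidation_factor >= 0, consolidation_factor <= 1)
  if (consolidation_factor == 1) return(policy)
  p <- policy
  p$noise_sigma0 <- policy$noise_sigma0 * consolidation_factor
  p$warm_start_runs <- policy$warm_start_runs + day1_runs
  # anticipatory station-keeping develops quickly with consolidation and
  # saturates: full strength once half the behavioral noise has contracted
  p$tonic_anticipation <- min(1, 2 * (1 - consolidation_factor))
  p
}

#' Simulate a paired two-day (consolidation) experiment
#'
#' Day 1 is a full multi-block conditioning session; day 2 is a contracted
#' single-block retraining session with the same Block-1 cue, simulated
#' under the [day2_policy()] derived from each fish's day-1 policy.
#'
#' @param n_fish Number of fish.
#' @param config An [experiment_config()].
#' @param sampler A [policy_sampler()] (or fixed `fish_policy`).
#' @param consolidation_factor Passed to [day2_policy()].
#' @param seed Master integer seed.
#' @return A list with elements `day1` and `day2`, each a list of
#'   `simulated_session` objects paired by position and fish id.
#' @export
simulate_two_day <- function(n_fish, config = experiment_config(),
                             sampler = policy_sampler(),
                             consolidation_factor = 0.5, seed = 1L) {
  if (inherits(sampler, "fish_policy")) {
    base <- sampler
    sampler <- function(seed) base
  }
  fish_seeds <- with_local_seed(seed,
                                sample.int(.Machine$integer.max, 4L * n_fish))
  day1 <- vector("list", n_fish)
  day2 <- vector("list", n_fish)
  for (i in seq_len(n_fish)) {
    id <- sprintf("fish%02d", i)
    pol <- sampler(fish_seeds[4L * i - 3L])
    tl1 <- build_timeline(config, seed = fish_seeds[4L * i - 3L])
    day1[[i]] <- simulate_session(pol, tl1, config$tank, config$fps,
                                  seed = fish_seeds[4L * i - 2L], fish_id = id)
    cue1 <- tl1$cue[tl1$epoch_kind == "cs"][1]
    tl2 <- build_timeline(config, seed = fish_seeds[4L * i - 1L],
                          cue_sequence = rep(cue1, config$runs_per_block),
                          n_blocks = 1L)
    p2 <- day2_policy(pol, consolidation_factor,
                      day1_runs = config$n_blocks * config$runs_per_block)
    day2[[i]] <- simulate_session(p2, tl2, config$tank, config$fps,
                                  seed = fish_seeds[4L * i], fish_id = id)
  }
  list(day1 = day1, day2 = day2)
}
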