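# Kinematic series, filtering rules, directional bias, longest trajectory.

test_that("compute_series recovers speeds for canonical motions", {
  st <- straight_approach_frames(n = 2, speed = 0)
  st$head_x <- rep(100, 2)
  expect_true(all(compute_series(st, 10)$speed == 0))

  ap <- compute_series(straight_approach_frames(speed = 10), 10)
  expect_equal(ap$speed, rep(10, nrow(ap)))
  expect_equal(ap$toward_step, rep(1, nrow(ap)))

  circ <- compute_series(circle_frames(r = 30, omega = 1, fps = 10), 10)
  # chord-length speed ~ r*omega for small angular steps
  expect_equal(mean(circ$speed), 30 * 1, tolerance = 0.01)

  expect_error(compute_series(straight_approach_frames(n = 1), 10),
               "at least 2")
})

test_that("edge filter implements the published margins", {
  tank <- tank_geometry()
  fr <- data.frame(fish_id = "f", head_x = seq(0.5, 249.5, by = 1),
                   head_y = 65)
  expect_equal(nrow(filter_edges(fr, 0, 0, tank)), nrow(fr))
  # uniform 1 mm grid of 250 frames, margins (backend 10, screen 20):
  # retained are 20 <= x <= 240 -> 221 by enumeration
  expect_equal(nrow(filter_edges(fr, 10, 20, tank)),
               sum(fr$head_x >= 20 & fr$head_x <= 240))
  expect_equal(nrow(filter_edges(fr, 10, 20, tank)), 220L)
  glued <- data.frame(fish_id = "f", head_x = 0, head_y = 65)
  expect_equal(nrow(filter_edges(glued, 10, 20, tank)), 0L)
})

test_that("activity filter retains strictly-faster frames only", {
  s <- toy_series(speed = c(10, 17, 16, 20), toward_step = rep(1, 4))
  expect_equal(nrow(filter_activity(s, 16)), 2L)
  expect_equal(nrow(filter_activity(s, 0)), 4L)
  still <- toy_series(speed = rep(0, 5), toward_step = rep(0, 5))
  expect_equal(nrow(filter_activity(still, 16)), 0L)
})

test_that("filters are idempotent and order-stable", {
  set.seed(42)
  fr <- data.frame(fish_id = "f",
                   head_x = runif(200, 0, 250), head_y = runif(200, 0, 130),
                   speed = rexp(200, 1 / 20), toward_step = rnorm(200))
  tank <- tank_geometry()
  e <- function(x) filter_edges(x, 10, 20, tank)
  a <- function(x) filter_activity(x, 16)
  expect_identical(e(e(fr)), e(fr))
  expect_identical(a(a(fr)), a(fr))
  expect_identical(a(e(fr)), e(a(fr)))
})

test_that("directional bias follows its definition and sign convention", {
  still <- toy_series(speed = rep(0, 20), toward_step = rep(0, 20))
  expect_equal(directional_bias(still, 10, 2), 0)
  # motion parallel to the screen: speed > 0 but zero toward-step
  par <- toy_series(speed = rep(15, 20), toward_step = rep(0, 20))
  expect_equal(directional_bias(par, 10, 2), 0)
  # constant approach at 10 mm/s, 10 fps: step 1 mm x speed 10 mm/s = 10
  ap <- compute_series(straight_approach_frames(speed = 10), 10)
  expect_equal(directional_bias(ap, 10, 2), 10)
  empty <- ap[0, ]
  expect_true(is.na(directional_bias(empty, 10, 2)))
  # sign equals -sign(d_end - d_start) for monotone paths
  retreat <- compute_series(within(straight_approach_frames(speed = 8),
                                   head_x <- rev(head_x)), 10)
  expect_lt(directional_bias(retreat, 10, 2), 0)
})

test_that("longest_trajectory picks the dominant constant-direction bout", {
  # monotone approach over a whole 3 s gap
  ap <- compute_series(straight_approach_frames(n = 30, speed = 10), 10)
  lt <- longest_trajectory(ap, 10)
  expect_equal(lt$direction, 1)
  expect_equal(lt$duration, 3)
  # 1 s approach then 2 s retreat -> away bout wins
  s <- toy_series(speed = rep(10, 30),
                  toward_step = c(rep(1, 10), rep(-1, 20)))
  lt2 <- longest_trajectory(s, 10)
  expect_equal(lt2$direction, -1)
  expect_equal(lt2$duration, 2)
  # all frames below the speed floor -> flagged missing
  slow <- toy_series(speed = rep(3, 30), toward_step = rep(1, 30))
  expect_true(is.na(longest_trajectory(slow, 10, min_speed = 16)$direction))
  # duration never exceeds the gap
  set.seed(7)
  for (i in 1:20) {
    rnd <- toy_series(speed = rexp(30, 1 / 20), toward_step = rnorm(30))
    expect_lte(longest_trajectory(rnd, 10)$duration, 3)
  }
  # isolated single-frame sign flips are absorbed
  s3 <- toy_series(speed = rep(10, 30),
                   toward_step = c(rep(1, 14), -1, rep(1, 15)))
  expect_equal(longest_trajectory(s3, 10)$duration, 3)
})

test_that("feature extraction flags missing metrics instead of imputing", {
  cfg <- fast_config()
  tl <- build_timeline(cfg, seed = 1, cue_sequence = rep("NCF", 18))
  pol <- fish_policy(base_speed_mean = 0, noise_sigma0 = 0,
                     approach_gain_max = 8, attention_amplitude = 0,
                     hysteresis_frames = 0, wall_margin = 0)
  ses <- simulate_session(pol, tl, cfg$tank, seed = 1)
  f <- extract_features(ses, cfg)
  # noiseless approacher: positive bias where defined
  expect_true(all(f$directional_bias[!is.na(f$directional_bias)] >= 0))
  # once parked at the screen wall (inside the margin) metrics go missing
  expect_true(any(is.na(f$distance_from_screen)))
  expect_equal(nrow(f), 18L)
})

test_that("frame pooling returns filtered per-frame rows", {
  cfg <- fast_config()
  ses <- simulate_cohort(3, cfg, seed = 9)
  ff <- extract_features_cohort(ses, cfg, pooling = "frame", runs = 13:18)
  expect_true(all(ff$activity > cfg$activity_threshold))
  expect_true(all(ff$distance >= cfg$screen_margin &
                    ff$distance <= cfg$tank$length - cfg$backend_margin))
  expect_true(all(ff$run_index >= 13))
  fz <- extract_features_cohort(ses, cfg, pooling = "frame", runs = 13:18,
                                zone = c(50, 150))
  expect_true(all(fz$distance >= 50 & fz$distance <= 150))
  expect_lte(nrow(fz), nrow(ff))
})
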