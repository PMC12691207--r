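# Shared fixture builders. Unit tests of the mechanics use a shortened
# timeline (brief ITIs and baselines) so the suite stays fast; the
# acceptance tests run the full study-condition timeline.

fast_config <- function(...) {
  experiment_config(iti_range = c(8, 12), session_baseline_duration = 30,
                    us_duration = 5, ...)
}

# hand-built tracking table: straight approach toward the screen at
# constant speed (mm/s), 10 fps, starting at x0
straight_approach_frames <- function(n = 30, speed = 10, fps = 10,
                                     x0 = 150, y = 65) {
  x <- x0 - (seq_len(n) - 1) * speed / fps
  data.frame(fish_id = "f1", frame_index = seq_len(n) - 1L,
             time = (seq_len(n) - 1) / fps, head_x = x, head_y = y,
             tail_x = x + 10, tail_y = y, heading = pi)
}

circle_frames <- function(n = 200, r = 30, omega = 1, fps = 10,
                          cx = 125, cy = 65) {
  t <- (seq_len(n) - 1) / fps
  data.frame(fish_id = "f1", frame_index = seq_len(n) - 1L, time = t,
             head_x = cx + r * cos(omega * t), head_y = cy + r * sin(omega * t),
             tail_x = NA_real_, tail_y = NA_real_,
             heading = omega * t + pi / 2)
}

# series data.frame directly (bypassing position differencing)
toy_series <- function(speed, toward_step, time = NULL, fps = 10) {
  n <- length(speed)
  data.frame(time = if (is.null(time)) (seq_len(n) - 1) / fps else time,
             distance = 100 - cumsum(c(0, toward_step[-n])),
             speed = speed, toward_step = toward_step,
             yaw = rep(0, n))
}

# brute-force signed-rank null distribution: all 2^n sign assignments
enumerate_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  W <- sum(r[d > 0])
  list(W = W,
       p_two = min(1, 2 * min(mean(w_all <= W + 1e-9),
                              mean(w_all >= W - 1e-9))),
       p_greater = mean(w_all >= W - 1e-9))
}

# brute-force rank-sum null distribution: all choose(N, n_a) assignments
enumerate_rank_sum <- function(a, b) {
  r <- rank(c(a, b), ties.method = "average")
  n_a <- length(a)
  Ra <- sum(r[seq_len(n_a)])
  sums <- combn(length(r), n_a, function(i) sum(r[i]))
  list(Ra = Ra,
       p_two = min(1, 2 * min(mean(sums <= Ra + 1e-9),
                              mean(sums >= Ra - 1e-9))))
}

# pair-counting AUC oracle
pair_count_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
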