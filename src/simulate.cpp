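#include <Rcpp.h>
using namespace Rcpp;

// Correlated-random-walk swim simulator. One call simulates a whole session
// at fixed fps. Per-frame drift (mm/s along the screen axis, positive = away
// from the screen) and turning-noise sigma (rad/frame) are precomputed in R
// from the timeline and learning/attention schedules; this loop only
// integrates the kinematics with reflecting walls and an inward bias inside
// the wall margin. Uses R's RNG, so results are reproducible under set.seed.
// [[Rcpp::export]]
List simulate_frames_cpp(int n_frames, double dt,
                         NumericVector drift, NumericVector sigma,
                         double speed_meanlog, double speed_sdlog,
                         bool zero_speed, double persistence,
                         double wall_margin, double inward_gain,
                         double L, double W,
                         double x0, double y0, double theta0) {
  NumericVector x(n_frames), y(n_frames), heading(n_frames);
  double xx = x0, yy = y0, theta = theta0, turn = 0.0, head = theta0;
  for (int i = 0; i < n_frames; ++i) {
    double speed = zero_speed ? 0.0 : ::exp(::Rf_rnorm(speed_meanlog, speed_sdlog));
    double s = sigma[i];
    turn = persistence * turn + (s > 0 ? ::Rf_rnorm(0.0, s) : 0.0);
    theta += turn;
    double vx = speed * ::cos(theta) + drift[i];
    double vy = speed * ::sin(theta);
    if (wall_margin > 0) {
      if (xx < wall_margin)      vx += inward_gain * (wall_margin - xx) / wall_margin;
      if (xx > L - wall_margin)  vx -= inward_gain * (xx - (L - wall_margin)) / wall_margin;
      if (yy < wall_margin)      vy += inward_gain * (wall_margin - yy) / wall_margin;
      if (yy > W - wall_margin)  vy -= inward_gain * (yy - (W - wall_margin)) / wall_margin;
    }
    double px = xx, py = yy;
    xx += vx * dt;
    yy += vy * dt;
    // specular reflection at the tank walls
    for (int k = 0; k < 4 && (xx < 0 || xx > L); ++k) {
      if (xx < 0) { xx = -xx; theta = M_PI - theta; }
      if (xx > L) { xx = 2 * L - xx; theta = M_PI - theta; }
    }
    for (int k = 0; k < 4 && (yy < 0 || yy > W); ++k) {
      if (yy < 0) { yy = -yy; theta = -theta; }
      if (yy > W) { yy = 2 * W - yy; theta = -theta; }
    }
    if (xx < 0) xx = 0; if (xx > L) xx = L;
    if (yy < 0) yy = 0; if (yy > W) yy = W;
    double dx = xx - px, dy = yy - py;
    if (dx != 0.0 || dy != 0.0) head = ::atan2(dy, dx);
    x[i] = xx; y[i] = yy; heading[i] = head;
  }
  return List::create(_["x"] = x, _["y"] = y, _["heading"] = heading);
}
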