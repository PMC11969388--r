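#include <Rcpp.h>
using namespace Rcpp;

// Two-state (active/inactive) correlated random walk inside a circular arena.
// Active frames take a fixed step at the ant's active speed with a heading
// that diffuses by a wrapped-normal turning kernel; inactive frames do not
// move. The boundary is reflecting: a proposed point at radius r > R is
// mapped radially to 2R - r (clamped to R for pathological steps larger
// than the arena). Uses R's RNG so results obey set.seed().
//
// [[Rcpp::export]]
DataFrame walk_cpp(int n_frames, double x0, double y0, double p_on,
                   double p_off, double step, double turn_sd, double radius) {
  NumericVector x(n_frames), y(n_frames);
  double cx = x0, cy = y0;
  double heading = unif_rand() * 2.0 * M_PI;
  bool active = unif_rand() < p_on / (p_on + p_off); // stationary start state
  for (int i = 0; i < n_frames; ++i) {
    if (active) {
      heading += norm_rand() * turn_sd;
      double nx = cx + step * std::cos(heading);
      double ny = cy + step * std::sin(heading);
      double r = std::sqrt(nx * nx + ny * ny);
      if (r > radius) {
        double rr = 2.0 * radius - r;
        if (rr < 0.0) rr = radius;
        if (rr > radius) rr = radius;
        nx *= rr / r;
        ny *= rr / r;
        heading += M_PI; // head back inwards after the bounce
      }
      cx = nx;
      cy = ny;
    }
    x[i] = cx;
    y[i] = cy;
    active = active ? (unif_rand() >= p_off) : (unif_rand() < p_on);
  }
  return DataFrame::create(_["x"] = x, _["y"] = y);
}

// Sequential aberrance scan: walking forward through one ant's frames, a
// position is aberrant when the straight-line speed from the last accepted
// position exceeds v_max (elapsed time accounts for intervening missing
// frames). Missing positions are skipped; the first valid position anchors
// the scan.
//
// [[Rcpp::export]]
LogicalVector flag_aberrant_cpp(IntegerVector frame, NumericVector x,
                                NumericVector y, LogicalVector missing,
                                double fps, double v_max) {
  int n = frame.size();
  LogicalVector aberrant(n, false);
  int anchor = -1;
  for (int i = 0; i < n; ++i) {
    if (missing[i]) continue;
    if (anchor < 0) {
      anchor = i;
      continue;
    }
    double dt = (frame[i] - frame[anchor]) / fps;
    double dx = x[i] - x[anchor];
    double dy = y[i] - y[anchor];
    double speed = std::sqrt(dx * dx + dy * dy) / dt;
    if (speed > v_max) {
      aberrant[i] = true;
    } else {
      anchor = i;
    }
  }
  return aberrant;
}
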