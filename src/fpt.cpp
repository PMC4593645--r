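#include <Rcpp.h>
using namespace Rcpp;

// Time to first exit of the circle of radius r centred at (cx, cy), walking
// from vertex i0 in direction dir (+1 forward, -1 backward) along the
// polyline (x, y) with per-vertex times tt (hours). Exit found by exact
// segment-circle intersection; time prorated linearly within the segment.
// Returns NA when the path ends inside the circle.
static double exit_time(const NumericVector& x, const NumericVector& y,
                        const NumericVector& tt, int i0, int dir, double r) {
  const int n = x.size();
  const double cx = x[i0], cy = y[i0];
  const double r2 = r * r;
  int i = i0;
  while (true) {
    int j = i + dir;
    if (j < 0 || j >= n) return NA_REAL;
    double ax = x[i] - cx, ay = y[i] - cy;
    double bx = x[j] - cx, by = y[j] - cy;
    double db2 = bx * bx + by * by;
    if (db2 > r2) {
      // crossing inside segment [i, j]: solve |a + s(b-a)|^2 = r^2 for s
      double dx = bx - ax, dy = by - ay;
      double A = dx * dx + dy * dy;
      double B = 2.0 * (ax * dx + ay * dy);
      double C = ax * ax + ay * ay - r2;
      double s = 1.0;
      if (A > 0.0) {
        double disc = B * B - 4.0 * A * C;
        if (disc < 0.0) disc = 0.0;
        s = (-B + std::sqrt(disc)) / (2.0 * A);
        if (s < 0.0) s = 0.0;
        if (s > 1.0) s = 1.0;
      }
      double t_cross = tt[i] + s * (tt[j] - tt[i]);
      return std::fabs(t_cross - tt[i0]);
    }
    i = j;
  }
}

// [[Rcpp::export(name = ".fpt_cpp")]]
NumericVector fpt_cpp(NumericVector x, NumericVector y, NumericVector tt,
                      double r) {
  const int n = x.size();
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    double fwd = exit_time(x, y, tt, i, +1, r);
    if (ISNA(fwd)) continue;
    double bwd = exit_time(x, y, tt, i, -1, r);
    if (ISNA(bwd)) continue;
    out[i] = fwd + bwd;
  }
  return out;
}

// Gaussian kernel density over grid centres (gx, gy) from points (px, py),
// isotropic bandwidth h. Coordinates and h share units (km). Unnormalized
// up to the common 1/(2*pi*h^2*n) factor applied here; grid renormalization
// happens in R.
// [[Rcpp::export(name = ".kde_cpp")]]
NumericVector kde_cpp(NumericVector px, NumericVector py,
                      NumericVector gx, NumericVector gy, double h) {
  const int n = px.size(), m = gx.size();
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double norm = 1.0 / (2.0 * M_PI * h * h * n);
  NumericVector out(m);
  for (int g = 0; g < m; ++g) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = gx[g] - px[i], dy = gy[g] - py[i];
      s += std::exp(-(dx * dx + dy * dy) * inv2h2);
    }
    out[g] = s * norm;
  }
  return out;
}
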