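#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Crossing parameters s in (0,1) of segment p0->p1 with the circle boundary.
// Tangency (discriminant <= 0) is not a crossing: a grazing contact never
// changes in/out state under the closed-disc convention.
static inline int seg_circle(double x0, double y0, double x1, double y1,
                             double cx, double cy, double r2,
                             double *s_lo, double *s_hi) {
  const double dx = x1 - x0, dy = y1 - y0;
  const double a = dx * dx + dy * dy;
  if (a <= 0.0) return 0;
  const double fx = x0 - cx, fy = y0 - cy;
  const double b = 2.0 * (fx * dx + fy * dy);
  const double c = fx * fx + fy * fy - r2;
  const double disc = b * b - 4.0 * a * c;
  if (disc <= 0.0) return 0;
  const double sq = std::sqrt(disc);
  double s1 = (-b - sq) / (2.0 * a);
  double s2 = (-b + sq) / (2.0 * a);
  int n = 0;
  if (s1 > 0.0 && s1 < 1.0) { *s_lo = s1; n++; }
  if (s2 > 0.0 && s2 < 1.0) { if (n) *s_hi = s2; else *s_lo = s2; n++; }
  if (n == 2 && *s_hi <= *s_lo) n = 1;
  return n;
}

// Maximal in-circle intervals of a time-sorted track w.r.t. one centre,
// merged when the outside gap is < min_away. Fix-on-boundary counts inside.
static void detect_one(const double *t, const double *x, const double *y,
                       int n, double cx, double cy, double r, double min_away,
                       std::vector<double> &enter, std::vector<double> &exit_) {
  enter.clear(); exit_.clear();
  const double r2 = r * r;
  double dx0 = x[0] - cx, dy0 = y[0] - cy;
  double d0 = dx0 * dx0 + dy0 * dy0;
  bool in0 = d0 <= r2;
  bool open = false;
  double t_open = 0.0;
  std::vector<double> re, rx; // raw intervals
  if (in0) { open = true; t_open = t[0]; }
  for (int i = 0; i + 1 < n; ++i) {
    const double dx1 = x[i + 1] - cx, dy1 = y[i + 1] - cy;
    const double d1 = dx1 * dx1 + dy1 * dy1;
    const bool in1 = d1 <= r2;
    const double dt = t[i + 1] - t[i];
    double s_lo, s_hi;
    if (!in0 && !in1) {
      // quick reject: closest approach >= dist(endpoint) - seg length
      const double sx = x[i + 1] - x[i], sy = y[i + 1] - y[i];
      const double L2 = sx * sx + sy * sy;
      const double rl = r + std::sqrt(L2);
      if (d0 <= rl * rl) {
        if (seg_circle(x[i], y[i], x[i + 1], y[i + 1], cx, cy, r2,
                       &s_lo, &s_hi) == 2) {
          re.push_back(t[i] + s_lo * dt);
          rx.push_back(t[i] + s_hi * dt);
        }
      }
    } else if (in0 && !in1) {
      int k = seg_circle(x[i], y[i], x[i + 1], y[i + 1], cx, cy, r2,
                         &s_lo, &s_hi);
      double tx = (k >= 1) ? t[i] + (k == 2 ? s_hi : s_lo) * dt : t[i];
      if (open) { re.push_back(t_open); rx.push_back(tx); open = false; }
    } else if (!in0 && in1) {
      int k = seg_circle(x[i], y[i], x[i + 1], y[i + 1], cx, cy, r2,
                         &s_lo, &s_hi);
      t_open = (k >= 1) ? t[i] + s_lo * dt : t[i + 1];
      open = true;
    } // inside->inside: chord of a disc stays inside (convexity)
    d0 = d1; in0 = in1;
  }
  if (open) { re.push_back(t_open); rx.push_back(t[n - 1]); }
  // merge gaps strictly shorter than min_away
  const size_t m = re.size();
  for (size_t i = 0; i < m; ++i) {
    if (!enter.empty() && re[i] - exit_.back() < min_away) {
      exit_.back() = rx[i];
    } else {
      enter.push_back(re[i]);
      exit_.push_back(rx[i]);
    }
  }
}

// [[Rcpp::export]]
List cpp_detect_visits(NumericVector t, NumericVector x, NumericVector y,
                       double cx, double cy, double radius, double minAway) {
  std::vector<double> en, ex;
  detect_one(REAL(t), REAL(x), REAL(y), t.size(), cx, cy, radius, minAway,
             en, ex);
  return List::create(_["tEnter"] = NumericVector(en.begin(), en.end()),
                      _["tExit"] = NumericVector(ex.begin(), ex.end()));
}

// Moving-circle recursion: one site per fix, visits of the same individual's
// track to the circle at that fix.
// [[Rcpp::export]]
List cpp_revisit_table(NumericVector t, NumericVector x, NumericVector y,
                       double radius, double minAway, bool storeVisits) {
  const int n = t.size();
  IntegerVector nv(n);
  std::vector<double> ven, vex;
  std::vector<int> vsite;
  std::vector<double> en, ex;
  for (int j = 0; j < n; ++j) {
    detect_one(REAL(t), REAL(x), REAL(y), n, x[j], y[j], radius, minAway,
               en, ex);
    nv[j] = (int)en.size();
    if (storeVisits) {
      for (size_t k = 0; k < en.size(); ++k) {
        vsite.push_back(j + 1);
        ven.push_back(en[k]);
        vex.push_back(ex[k]);
      }
    }
  }
  if (storeVisits)
    return List::create(_["nVisits"] = nv,
                        _["site"] = IntegerVector(vsite.begin(), vsite.end()),
                        _["tEnter"] = NumericVector(ven.begin(), ven.end()),
                        _["tExit"] = NumericVector(vex.begin(), vex.end()));
  return List::create(_["nVisits"] = nv);
}

// Minimum distance from each point to a set of segments and lone points.
// [[Rcpp::export]]
NumericVector cpp_dist_to_segments(NumericVector px, NumericVector py,
                                   NumericVector x1, NumericVector y1,
                                   NumericVector x2, NumericVector y2,
                                   NumericVector qx, NumericVector qy) {
  const int np = px.size(), ns = x1.size(), nq = qx.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    const double X = px[i], Y = py[i];
    for (int j = 0; j < ns; ++j) {
      const double dx = x2[j] - x1[j], dy = y2[j] - y1[j];
      const double L2 = dx * dx + dy * dy;
      double s = 0.0;
      if (L2 > 0.0) {
        s = ((X - x1[j]) * dx + (Y - y1[j]) * dy) / L2;
        if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
      }
      const double ex = X - (x1[j] + s * dx), ey = Y - (y1[j] + s * dy);
      const double d = ex * ex + ey * ey;
      if (d < best) best = d;
    }
    for (int j = 0; j < nq; ++j) {
      const double ex = X - qx[j], ey = Y - qy[j];
      const double d = ex * ex + ey * ey;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Even-odd point-in-polygon (boundary points may fall either side; callers
// that care pair this with a boundary-distance test).
// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericVector px, NumericVector py,
                                 NumericVector vx, NumericVector vy) {
  const int np = px.size(), nv = vx.size();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    bool in = false;
    const double X = px[i], Y = py[i];
    for (int j = 0, k = nv - 1; j < nv; k = j++) {
      if (((vy[j] > Y) != (vy[k] > Y)) &&
          (X < (vx[k] - vx[j]) * (Y - vy[j]) / (vy[k] - vy[j]) + vx[j]))
        in = !in;
    }
    out[i] = in;
  }
  return out;
}
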