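#include <Rcpp.h>
#include <deque>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Hartigan-style dip statistic: minimal sup-norm distance between the ECDF
// and a nondecreasing, convex-then-concave (unimodal) CDF.  Feasibility at a
// given half-width d is decided by stretching a taut string ("shortest path")
// through the vertical gates the band induces at the data knots and checking
// that its slope sequence rises then falls.  The dip is found by bisection.

struct Pt {
  double x, y;
};

static inline double slp(const Pt& a, const Pt& b) {
  return (b.y - a.y) / (b.x - a.x);
}

// Shortest Euclidean path through vertical gates (x strictly increasing).
// First and last gates must be pinned (lo == hi).  Returns the bend points.
static std::vector<Pt> taut_path(const std::vector<double>& x,
                                 const std::vector<double>& lo,
                                 const std::vector<double>& hi) {
  const int m = (int)x.size();
  std::vector<Pt> path;
  Pt apex{x[0], lo[0]};
  path.push_back(apex);
  // up: ceiling pegs, kept as a convex chain (slopes increasing)
  // dn: floor pegs, kept as a concave chain (slopes decreasing)
  std::deque<Pt> up, dn;
  for (int i = 1; i < m; ++i) {
    Pt T{x[i], hi[i]};
    Pt B{x[i], lo[i]};
    // ---- ceiling point
    while (up.size() >= 2 &&
           slp(up[up.size() - 2], up[up.size() - 1]) >= slp(up[up.size() - 1], T))
      up.pop_back();
    if (up.size() == 1 && slp(apex, up[0]) >= slp(up[0], T)) up.pop_back();
    if (up.empty()) {
      while (!dn.empty() && slp(apex, T) < slp(apex, dn.front())) {
        apex = dn.front();
        dn.pop_front();
        path.push_back(apex);
      }
    }
    up.push_back(T);
    // ---- floor point
    while (dn.size() >= 2 &&
           slp(dn[dn.size() - 2], dn[dn.size() - 1]) <= slp(dn[dn.size() - 1], B))
      dn.pop_back();
    if (dn.size() == 1 && slp(apex, dn[0]) <= slp(dn[0], B)) dn.pop_back();
    if (dn.empty()) {
      while (!up.empty() && slp(apex, B) > slp(apex, up.front())) {
        apex = up.front();
        up.pop_front();
        path.push_back(apex);
      }
    }
    dn.push_back(B);
  }
  path.push_back(Pt{x[m - 1], lo[m - 1]});
  return path;
}

// Is the slope sequence of the path increasing-then-decreasing?  Slopes that
// differ by less than a relative tolerance are treated as ties.
static bool slopes_unimodal(const std::vector<Pt>& path) {
  const int m = (int)path.size();
  bool descending = false;
  double prev = slp(path[0], path[1]);
  for (int i = 1; i + 1 < m; ++i) {
    double s = slp(path[i], path[i + 1]);
    double eps = 1e-9 * (std::fabs(s) + std::fabs(prev)) + 1e-12;
    if (s < prev - eps) {
      descending = true;
    } else if (s > prev + eps && descending) {
      return false;
    }
    prev = s;
  }
  return true;
}

// As above but with the peak forced into the open interval (xl, xr): slopes of
// segments entirely left of xl must be increasing, those entirely right of xr
// decreasing (used when a jump at a tied knot serves as the mode).
static bool slopes_unimodal_forced(const std::vector<Pt>& path,
                                   double xl, double xr) {
  const int m = (int)path.size();
  double prev_l = R_NegInf, prev_r = R_PosInf;
  for (int i = 0; i + 1 < m; ++i) {
    double s = slp(path[i], path[i + 1]);
    double eps = 1e-9 * std::fabs(s) + 1e-12;
    if (path[i + 1].x <= xl) {
      if (s < prev_l - eps) return false;
      prev_l = s;
    } else if (path[i].x >= xr) {
      if (s > prev_r + eps) return false;
      prev_r = s;
    }
  }
  return true;
}

struct Knots {
  std::vector<double> x;     // unique values, scaled to [0, 1]
  std::vector<double> cum;   // ECDF value at the knot (c_j / n)
  std::vector<double> pre;   // ECDF left limit ((c_{j-1}) / n)
  std::vector<int> mult;     // multiplicity
};

static Knots make_knots(const NumericVector& xs) {
  Knots k;
  const int n = xs.size();
  const double x0 = xs[0], span = xs[n - 1] - xs[0];
  const double sc = span > 0 ? 1.0 / span : 1.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && xs[j + 1] == xs[i]) ++j;
    k.x.push_back((xs[i] - x0) * sc);
    k.pre.push_back((double)i / n);
    k.cum.push_back((double)(j + 1) / n);
    k.mult.push_back(j - i + 1);
    i = j + 1;
  }
  return k;
}

// Feasibility of half-width d.  jump = -1: continuous unimodal CDF.
// jump = j >= 0: a single vertical jump (atom at the mode) is allowed at
// knot j, realised as a split gate with the slope peak forced there.
static bool dip_feasible(const Knots& k, double d, int jump) {
  const double A = 1e5;  // anchor distance; boundary slopes ~ 1/A
  const int m = (int)k.x.size();
  std::vector<double> gx, glo, ghi;
  gx.reserve(m + 3);
  glo.reserve(m + 3);
  ghi.reserve(m + 3);
  gx.push_back(-A);
  glo.push_back(0.0);
  ghi.push_back(0.0);
  double xl = 0, xr = 0;
  const double delta = 1e-7;  // width of the split gate carrying a jump
  for (int j = 0; j < m; ++j) {
    if (j == jump) {
      xl = k.x[j] - delta;
      xr = k.x[j] + delta;
      gx.push_back(xl);
      glo.push_back(std::max(0.0, k.pre[j] - d));
      ghi.push_back(std::min(1.0, k.pre[j] + d));
      gx.push_back(xr);
      glo.push_back(std::max(0.0, k.cum[j] - d));
      ghi.push_back(std::min(1.0, k.cum[j] + d));
    } else {
      double lo = std::max(0.0, k.cum[j] - d);
      double hi = std::min(1.0, k.pre[j] + d);
      if (lo > hi) return false;
      gx.push_back(k.x[j]);
      glo.push_back(lo);
      ghi.push_back(hi);
    }
  }
  gx.push_back(1.0 + A);
  glo.push_back(1.0);
  ghi.push_back(1.0);
  std::vector<Pt> path = taut_path(gx, glo, ghi);
  if (jump < 0) return slopes_unimodal(path);
  return slopes_unimodal_forced(path, xl, xr);
}

static double dip_sorted(const NumericVector& xs) {
  const int n = xs.size();
  if (n < 2) return 0.0;
  Knots k = make_knots(xs);
  const int m = (int)k.x.size();
  if (m == 1) return 0.0;  // all values tied: a point mass fits exactly
  // candidate positions for an atom at the mode: tied knots only (an atom at
  // a knot of multiplicity one never helps below the 1/(2n) gate bound)
  std::vector<int> jumps;
  jumps.push_back(-1);
  for (int j = 0; j < m; ++j)
    if (k.mult[j] > 1) jumps.push_back(j);
  double lo = 0.0, hi = 0.26;
  while (true) {
    bool ok = false;
    for (size_t q = 0; q < jumps.size() && !ok; ++q)
      ok = dip_feasible(k, hi, jumps[q]);
    if (ok) break;
    lo = hi;
    hi *= 2.0;
    if (hi > 1.0) return NA_REAL;  // cannot happen: d = 1 always feasible
  }
  for (int it = 0; it < 60 && (hi - lo) > 1e-11; ++it) {
    double mid = 0.5 * (lo + hi);
    bool ok = false;
    for (size_t q = 0; q < jumps.size() && !ok; ++q)
      ok = dip_feasible(k, mid, jumps[q]);
    if (ok)
      hi = mid;
    else
      lo = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  NumericVector xs = clone(x).sort();
  return dip_sorted(xs);
}

// Null distribution of the dip for samples of size n from a continuous
// distribution (uniform(0,1) draws; the dip is distribution-free under any
// continuous unimodal null in the sense used for calibration here).
// Uses R's RNG, so set.seed() makes it reproducible.
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int nboot) {
  NumericVector out(nboot);
  for (int b = 0; b < nboot; ++b) {
    NumericVector u = runif(n);
    u.sort();
    out[b] = dip_sorted(u);
  }
  return out;
}
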