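#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Fast-marching redistancing: rebuilds phi as an exact-to-first-order signed
// distance to its own zero level. Interface-adjacent cells are initialised
// with subcell distances from the linear interpolant (so the zero level is
// not displaced), then the Eikonal equation |grad phi| = 1 is solved outward
// on each side by the standard fast marching method.

struct FmGrid {
  int nx, ny, nz;
  bool periodic;
  R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
  // neighbour of i along axis a (dir = -1/+1); returns -1 off-grid
  R_xlen_t nb(R_xlen_t i, int a, int dir) const {
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
    int c[3] = {x, y, z};
    int m[3] = {nx, ny, nz};
    c[a] += dir;
    if (periodic) {
      if (c[a] < 0) c[a] += m[a];
      if (c[a] >= m[a]) c[a] -= m[a];
    } else if (c[a] < 0 || c[a] >= m[a]) {
      return -1;
    }
    return c[0] + (R_xlen_t)nx * (c[1] + (R_xlen_t)ny * c[2]);
  }
};

// solve for t with |grad| = 1 given accepted axis minima (INF if none)
static double eikonal_update(double a1, double a2, double a3, double h) {
  double v[3] = {a1, a2, a3};
  // sort ascending
  if (v[0] > v[1]) std::swap(v[0], v[1]);
  if (v[1] > v[2]) std::swap(v[1], v[2]);
  if (v[0] > v[1]) std::swap(v[0], v[1]);
  double t = v[0] + h;
  if (t <= v[1]) return t;
  double s = v[0] + v[1];
  double disc = 2 * h * h - (v[0] - v[1]) * (v[0] - v[1]);
  if (disc > 0) {
    t = 0.5 * (s + std::sqrt(disc));
    if (t <= v[2]) return t;
  }
  s = v[0] + v[1] + v[2];
  double q = v[0] * v[0] + v[1] * v[1] + v[2] * v[2] - h * h;
  disc = s * s - 3 * q;
  if (disc > 0) return (s + std::sqrt(disc)) / 3.0;
  return v[0] + h;  // fallback
}

// cap: stop marching beyond this distance; unreached cells keep their old
// magnitude, floored at the cap (they are only ever used as "far").
void fmm_redistance(std::vector<double>& p, int nx, int ny, int nz,
                    double h, bool periodic, double cap) {
  FmGrid g{nx, ny, nz, periodic};
  const R_xlen_t n = g.n();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n, INF);       // unsigned distance
  std::vector<char> sign(n), state(n, 0);  // state: 0 far, 1 trial, 2 accepted

  for (R_xlen_t i = 0; i < n; i++) sign[i] = p[i] > 0 ? 1 : 0;

  // subcell initialisation at the interface
  for (R_xlen_t i = 0; i < n; i++) {
    double c = p[i];
    double dmin = INF;
    for (int a = 0; a < 3; a++)
      for (int dir = -1; dir <= 1; dir += 2) {
        R_xlen_t j = g.nb(i, a, dir);
        if (j < 0) continue;
        double q = p[j];
        if ((c > 0) == (q > 0)) continue;
        double denom = std::fabs(c - q);
        if (denom < 1e-12) denom = 1e-12;
        double dc = h * std::fabs(c) / denom;
        if (dc < dmin) dmin = dc;
      }
    if (dmin < INF) {
      d[i] = dmin;
      state[i] = 2;
    }
  }

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

  // seed trial cells from accepted neighbours (per side)
  for (R_xlen_t i = 0; i < n; i++) {
    if (state[i] != 2) continue;
    for (int a = 0; a < 3; a++)
      for (int dir = -1; dir <= 1; dir += 2) {
        R_xlen_t j = g.nb(i, a, dir);
        if (j < 0 || state[j] == 2 || sign[j] != sign[i]) continue;
        double ax[3];
        for (int b = 0; b < 3; b++) {
          ax[b] = INF;
          for (int dd = -1; dd <= 1; dd += 2) {
            R_xlen_t k = g.nb(j, b, dd);
            if (k >= 0 && state[k] == 2 && sign[k] == sign[j] && d[k] < ax[b])
              ax[b] = d[k];
          }
        }
        double t = eikonal_update(ax[0], ax[1], ax[2], h);
        if (t < d[j]) {
          d[j] = t;
          state[j] = 1;
          heap.push(QE(t, j));
        }
      }
  }

  while (!heap.empty()) {
    QE top = heap.top();
    heap.pop();
    R_xlen_t i = top.second;
    if (state[i] == 2 || top.first > d[i]) continue;  // stale entry
    if (top.first > cap) break;
    state[i] = 2;
    for (int a = 0; a < 3; a++)
      for (int dir = -1; dir <= 1; dir += 2) {
        R_xlen_t j = g.nb(i, a, dir);
        if (j < 0 || state[j] == 2 || sign[j] != sign[i]) continue;
        double ax[3];
        for (int b = 0; b < 3; b++) {
          ax[b] = INF;
          for (int dd = -1; dd <= 1; dd += 2) {
            R_xlen_t k = g.nb(j, b, dd);
            if (k >= 0 && state[k] == 2 && sign[k] == sign[j] && d[k] < ax[b])
              ax[b] = d[k];
          }
        }
        double t = eikonal_update(ax[0], ax[1], ax[2], h);
        if (t < d[j]) {
          d[j] = t;
          if (state[j] == 0) state[j] = 1;
          heap.push(QE(t, j));
        }
      }
  }

  for (R_xlen_t i = 0; i < n; i++) {
    double m;
    if (state[i] == 2) {
      m = d[i];
    } else {
      m = std::fabs(p[i]);       // unreached: keep old magnitude as "far"
      if (std::isfinite(cap) && m < cap) m = cap;
      if (!std::isfinite(m)) m = std::isfinite(cap) ? cap : 0.0;
    }
    p[i] = sign[i] ? m : -m;
  }
}

// [[Rcpp::export(name = ".fmm_redistance_cpp")]]
NumericVector fmm_redistance_cpp(NumericVector phi, IntegerVector dim,
                                 double h, bool periodic, double cap) {
  std::vector<double> p(phi.begin(), phi.end());
  fmm_redistance(p, dim[0], dim[1], dim[2], h, periodic, cap);
  return NumericVector(p.begin(), p.end());
}
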