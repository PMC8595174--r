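#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Finite-difference level-set solver for curvature-driven tissue growth.
// phi is a signed distance field, positive in the solid-plus-tissue phase and
// negative in the ungrown void. The interface advances into the void with
// normal speed F = max(k, 0), where k = div(grad phi / |grad phi|) is the mean
// curvature (positive on surfaces concave as seen from the void). Time is the
// dimensionless curvature-flow time tau; physical days are tau / lambda.

void fmm_redistance(std::vector<double>& p, int nx, int ny, int nz,
                    double h, bool periodic, double cap);  // fmm.cpp

struct LSGrid {
  int nx, ny, nz;
  bool periodic;
  R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
  inline int wrap(int i, int m) const {
    if (periodic) {
      if (i < 0) return i + m;
      if (i >= m) return i - m;
      return i;
    }
    if (i < 0) return 0;
    if (i >= m) return m - 1;
    return i;
  }
  inline R_xlen_t idx(int x, int y, int z) const {
    return wrap(x, nx) + (R_xlen_t)nx * (wrap(y, ny) + (R_xlen_t)ny * wrap(z, nz));
  }
};

static inline double curvature_at(const std::vector<double>& p, const LSGrid& g,
                                  int x, int y, int z, double h) {
  const double inv2h = 1.0 / (2.0 * h), invh2 = 1.0 / (h * h),
               inv4h2 = 1.0 / (4.0 * h * h);
  double c = p[g.idx(x, y, z)];
  double pxp = p[g.idx(x + 1, y, z)], pxm = p[g.idx(x - 1, y, z)];
  double pyp = p[g.idx(x, y + 1, z)], pym = p[g.idx(x, y - 1, z)];
  double pzp = p[g.idx(x, y, z + 1)], pzm = p[g.idx(x, y, z - 1)];
  double px = (pxp - pxm) * inv2h, py = (pyp - pym) * inv2h,
         pz = (pzp - pzm) * inv2h;
  double g2 = px * px + py * py + pz * pz;
  if (g2 < 1e-16) return 0.0;
  double pxx = (pxp - 2.0 * c + pxm) * invh2;
  double pyy = (pyp - 2.0 * c + pym) * invh2;
  double pzz = (pzp - 2.0 * c + pzm) * invh2;
  double pxy = (p[g.idx(x + 1, y + 1, z)] - p[g.idx(x + 1, y - 1, z)] -
                p[g.idx(x - 1, y + 1, z)] + p[g.idx(x - 1, y - 1, z)]) * inv4h2;
  double pxz = (p[g.idx(x + 1, y, z + 1)] - p[g.idx(x + 1, y, z - 1)] -
                p[g.idx(x - 1, y, z + 1)] + p[g.idx(x - 1, y, z - 1)]) * inv4h2;
  double pyz = (p[g.idx(x, y + 1, z + 1)] - p[g.idx(x, y + 1, z - 1)] -
                p[g.idx(x, y - 1, z + 1)] + p[g.idx(x, y - 1, z - 1)]) * inv4h2;
  double num = pxx * (py * py + pz * pz) + pyy * (px * px + pz * pz) +
               pzz * (px * px + py * py) -
               2.0 * (px * py * pxy + px * pz * pxz + py * pz * pyz);
  return num / (g2 * std::sqrt(g2));
}

// smoothed Heaviside with half-width eps
static inline double heaviside(double phi, double eps) {
  if (phi > eps) return 1.0;
  if (phi < -eps) return 0.0;
  return 0.5 * (1.0 + phi / eps + std::sin(M_PI * phi / eps) / M_PI);
}

static double smoothed_volume(const std::vector<double>& p, double eps,
                              double voxvol) {
  double v = 0.0;
  for (size_t i = 0; i < p.size(); i++) v += heaviside(p[i], eps);
  return v * voxvol;
}

// Reinitialisation with the subcell (interface-pinning) fix: cells whose
// sign differs from a 6-neighbour are set to a linearly interpolated signed
// distance computed from the incoming field and frozen; the remaining cells
// relax toward |grad phi| = 1 with the usual upwind pseudo-time iterations.
// This restores the distance property without displacing the zero level.
static void reinit_sweeps(std::vector<double>& p, const LSGrid& g, double h,
                          int iters) {
  const R_xlen_t n = g.n();
  std::vector<double> p0(p), pn(n);
  std::vector<double> s(n);
  std::vector<char> iface(n, 0);
  for (R_xlen_t i = 0; i < n; i++)
    s[i] = p0[i] / std::sqrt(p0[i] * p0[i] + h * h);
  for (int z = 0; z < g.nz; z++)
    for (int y = 0; y < g.ny; y++)
      for (int x = 0; x < g.nx; x++) {
        R_xlen_t i = g.idx(x, y, z);
        double c = p0[i];
        bool cut = false;
        const R_xlen_t nb[6] = {g.idx(x - 1, y, z), g.idx(x + 1, y, z),
                                g.idx(x, y - 1, z), g.idx(x, y + 1, z),
                                g.idx(x, y, z - 1), g.idx(x, y, z + 1)};
        for (int m = 0; m < 6 && !cut; m++)
          if ((c > 0) != (p0[nb[m]] > 0)) cut = true;
        if (!cut) continue;
        iface[i] = 1;
        // normal distance |phi|/|grad phi| of the incoming field, bounded by
        // the nearest axial crossing of the linear interpolant (the gradient
        // estimate degenerates on single-cell pockets, where the crossing
        // bound takes over)
        double gx = (p0[nb[1]] - p0[nb[0]]) / (2 * h);
        double gy = (p0[nb[3]] - p0[nb[2]]) / (2 * h);
        double gz = (p0[nb[5]] - p0[nb[4]]) / (2 * h);
        double gr = std::sqrt(gx * gx + gy * gy + gz * gz);
        double dnorm = std::fabs(c) / std::max(gr, 0.2);
        double dmin = dnorm;
        for (int m = 0; m < 6; m++) {
          double q = p0[nb[m]];
          if ((c > 0) == (q > 0)) continue;
          double denom = std::fabs(c - q);
          if (denom < 1e-12) denom = 1e-12;
          double dcross = h * std::fabs(c) / denom;
          if (dcross < dmin) dmin = dcross;
        }
        p[i] = (c > 0 ? 1.0 : -1.0) * dmin;
      }
  double dtau = 0.5 * h;
  for (int it = 0; it < iters; it++) {
    for (int z = 0; z < g.nz; z++)
      for (int y = 0; y < g.ny; y++)
        for (int x = 0; x < g.nx; x++) {
          R_xlen_t i = g.idx(x, y, z);
          if (iface[i]) { pn[i] = p[i]; continue; }  // pinned at the interface
          double c = p[i];
          double a1 = (c - p[g.idx(x - 1, y, z)]) / h,
                 b1 = (p[g.idx(x + 1, y, z)] - c) / h;
          double a2 = (c - p[g.idx(x, y - 1, z)]) / h,
                 b2 = (p[g.idx(x, y + 1, z)] - c) / h;
          double a3 = (c - p[g.idx(x, y, z - 1)]) / h,
                 b3 = (p[g.idx(x, y, z + 1)] - c) / h;
          double G;
          if (p0[i] > 0) {
            double gx = std::max(std::max(a1, 0.0) * std::max(a1, 0.0),
                                 std::min(b1, 0.0) * std::min(b1, 0.0));
            double gy = std::max(std::max(a2, 0.0) * std::max(a2, 0.0),
                                 std::min(b2, 0.0) * std::min(b2, 0.0));
            double gz = std::max(std::max(a3, 0.0) * std::max(a3, 0.0),
                                 std::min(b3, 0.0) * std::min(b3, 0.0));
            G = std::sqrt(gx + gy + gz);
          } else {
            double gx = std::max(std::min(a1, 0.0) * std::min(a1, 0.0),
                                 std::max(b1, 0.0) * std::max(b1, 0.0));
            double gy = std::max(std::min(a2, 0.0) * std::min(a2, 0.0),
                                 std::max(b2, 0.0) * std::max(b2, 0.0));
            double gz = std::max(std::min(a3, 0.0) * std::min(a3, 0.0),
                                 std::max(b3, 0.0) * std::max(b3, 0.0));
            G = std::sqrt(gx + gy + gz);
          }
          pn[i] = c - dtau * s[i] * (G - 1.0);
        }
    p.swap(pn);
  }
}

// [[Rcpp::export(name = ".curvature_cpp")]]
NumericVector curvature_cpp(NumericVector phi, IntegerVector dim, double h,
                            bool periodic) {
  LSGrid g{dim[0], dim[1], dim[2], periodic};
  std::vector<double> p(phi.begin(), phi.end());
  NumericVector out((R_xlen_t)g.n());
  for (int z = 0; z < g.nz; z++)
    for (int y = 0; y < g.ny; y++)
      for (int x = 0; x < g.nx; x++) {
        R_xlen_t i = g.idx(x, y, z);
        out[i] = curvature_at(p, g, x, y, z, h);
      }
  return out;
}

// [[Rcpp::export(name = ".reinit_cpp")]]
NumericVector reinit_cpp(NumericVector phi, IntegerVector dim, double h,
                         bool periodic, int iters) {
  LSGrid g{dim[0], dim[1], dim[2], periodic};
  std::vector<double> p(phi.begin(), phi.end());
  reinit_sweeps(p, g, h, iters);
  return NumericVector(p.begin(), p.end());
}

// Advance the interface; returns sampled tissue curve and (if reached) the
// dimensionless fill time.
// [[Rcpp::export(name = ".growth_core_cpp")]]
List growth_core_cpp(NumericVector phi_in, IntegerVector dim, double h,
                     bool periodic, double dt, double tau_max, int max_steps,
                     double fill_threshold, bool stop_on_fill,
                     int redist_every, int reinit_iters, int out_every,
                     double band, double cfl) {
  LSGrid g{dim[0], dim[1], dim[2], periodic};
  const R_xlen_t n = g.n();
  std::vector<double> p(phi_in.begin(), phi_in.end());
  const double voxvol = h * h * h;
  const double eps = 1.5 * h;
  // Only curvatures whose radius is resolvable on the grid are trusted; the
  // clamp also bounds the CFL step. The speed field is evaluated only in a
  // tight interface band and only where the central gradient is
  // well-conditioned (distance-field ridges make the curvature stencil
  // singular; such cells carry no reliable interface information).
  const double k_clamp = 0.5 / h;
  const double grad2_min = 0.25;
  const double total_vol = (double)n * voxvol;

  double solid_vol0 = smoothed_volume(p, eps, voxvol);
  double void_vol0 = total_vol - solid_vol0;
  if (void_vol0 <= 0) stop("grid has no void to grow into");
  const double fill_target = void_vol0 * (1.0 - fill_threshold);

  std::vector<double> taus, tissues;
  std::vector<double> F(n);
  double tau = 0.0;
  double tissue = 0.0;
  taus.push_back(0.0);
  tissues.push_back(0.0);
  double fill_tau = NA_REAL;
  bool filled = false;

  int step = 0;
  int stalled_samples = 0;
  bool stalled = false;
  bool moved_since_reinit = false;
  double maxF = 0.0;
  while (step < max_steps && tau < tau_max && !(filled && stop_on_fill) &&
         !(stalled && stop_on_fill)) {
    // speed field on the narrow band
    maxF = 0.0;
    for (int z = 0; z < g.nz; z++)
      for (int y = 0; y < g.ny; y++)
        for (int x = 0; x < g.nx; x++) {
          R_xlen_t i = g.idx(x, y, z);
          double f = 0.0;
          double aphi = std::fabs(p[i]);
          if (aphi < band) {
            double px = (p[g.idx(x + 1, y, z)] - p[g.idx(x - 1, y, z)]) / (2 * h);
            double py = (p[g.idx(x, y + 1, z)] - p[g.idx(x, y - 1, z)]) / (2 * h);
            double pz = (p[g.idx(x, y, z + 1)] - p[g.idx(x, y, z - 1)]) / (2 * h);
            if (px * px + py * py + pz * pz >= grad2_min) {
              double k = curvature_at(p, g, x, y, z, h);
              if (k > 0) {
                f = std::min(k, k_clamp);
                // taper smoothly to zero over the outer half of the band: a
                // hard speed cut-off leaves a kink whose curvature noise
                // cascades back to the interface
                double a = aphi / band;
                if (a > 0.5) {
                  double w = std::cos(M_PI * (a - 0.5));
                  f *= w * w;
                }
              }
            } else if (aphi < 1.5 * h) {
              // sub-grid pocket: the central gradient degenerates at the
              // centre of a nearly swallowed void, which would freeze it one
              // cell short of filling; the 6-point Laplacian still signals
              // concavity reliably there
              double lap = p[g.idx(x + 1, y, z)] + p[g.idx(x - 1, y, z)] +
                           p[g.idx(x, y + 1, z)] + p[g.idx(x, y - 1, z)] +
                           p[g.idx(x, y, z + 1)] + p[g.idx(x, y, z - 1)] -
                           6.0 * p[i];
              if (lap > h) f = k_clamp;
            }
          }
          F[i] = f;
          if (f > maxF) maxF = f;
        }
    double dte = dt;
    if (maxF > 0) dte = std::min(dt, cfl * h / maxF);
    // curvature-driven speed is diffusive: explicit stepping also needs the
    // parabolic bound dt <= O(h^2) (in units of the unit velocity-curvature
    // coefficient) or grid-scale perturbations grow and race the interface
    double dt_parab = 0.1 * h * h;
    if (maxF > 0 && dte > dt_parab) dte = dt_parab;
    if (tau + dte > tau_max) dte = tau_max - tau;

    // upwind (Godunov, F >= 0) update
    for (int z = 0; z < g.nz; z++)
      for (int y = 0; y < g.ny; y++)
        for (int x = 0; x < g.nx; x++) {
          R_xlen_t i = g.idx(x, y, z);
          if (F[i] <= 0) continue;
          double c = p[i];
          double a1 = (c - p[g.idx(x - 1, y, z)]) / h,
                 b1 = (p[g.idx(x + 1, y, z)] - c) / h;
          double a2 = (c - p[g.idx(x, y - 1, z)]) / h,
                 b2 = (p[g.idx(x, y + 1, z)] - c) / h;
          double a3 = (c - p[g.idx(x, y, z - 1)]) / h,
                 b3 = (p[g.idx(x, y, z + 1)] - c) / h;
          // Godunov upwinding for growth of the positive (tissue) phase:
          // characteristics arrive from the tissue side
          double gx = std::min(a1, 0.0) * std::min(a1, 0.0) +
                      std::max(b1, 0.0) * std::max(b1, 0.0);
          double gy = std::min(a2, 0.0) * std::min(a2, 0.0) +
                      std::max(b2, 0.0) * std::max(b2, 0.0);
          double gz = std::min(a3, 0.0) * std::min(a3, 0.0) +
                      std::max(b3, 0.0) * std::max(b3, 0.0);
          p[i] = c + dte * F[i] * std::sqrt(gx + gy + gz);
        }
    tau += dte;
    step++;
    if (maxF > 0) moved_since_reinit = true;

    // redistance only when the field actually changed: reinitialising a
    // static field accumulates a slow interface drift for no benefit
    if (redist_every > 0 && step % redist_every == 0 && moved_since_reinit) {
      reinit_sweeps(p, g, h, reinit_iters);
      moved_since_reinit = false;
    }

    if (step % out_every == 0 || tau >= tau_max || step >= max_steps) {
      double prev_tau = taus.back(), prev_tissue = tissues.back();
      tissue = smoothed_volume(p, eps, voxvol) - solid_vol0;
      if (tissue < prev_tissue) tissue = prev_tissue; // guard reinit jitter
      taus.push_back(tau);
      tissues.push_back(tissue);
      if (!filled && tissue >= fill_target) {
        filled = true;
        double denom = tissue - prev_tissue;
        double w = denom > 0 ? (fill_target - prev_tissue) / denom : 1.0;
        fill_tau = prev_tau + w * (tau - prev_tau);
      }
      // plateau detection: growth has effectively frozen (flat or convex
      // residual surfaces have zero speed under the one-sided velocity rule)
      if (stop_on_fill && !filled) {
        if (tissue - prev_tissue < 1e-9 * void_vol0) stalled_samples++;
        else stalled_samples = 0;
        if (stalled_samples >= 200 || maxF < 1e-12) stalled = true;
      }
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["tau"] = NumericVector(taus.begin(), taus.end()),
      _["tissue"] = NumericVector(tissues.begin(), tissues.end()),
      _["fill_tau"] = fill_tau, _["filled"] = filled, _["stalled"] = stalled,
      _["steps"] = step,
      _["solid_vol0"] = solid_vol0, _["void_vol0"] = void_vol0,
      _["phi"] = NumericVector(p.begin(), p.end()));
}
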