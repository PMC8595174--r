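#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope-of-parabolas pass applied along each axis.

static const double DT_INF = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = 0.0;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance (voxel units) from every voxel to the nearest TRUE voxel.
// Voxels with no feature anywhere get a large sentinel (>= 1e29).
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (feature.size() != n) stop("feature length does not match dim");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = feature[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  }
  // pass along y
  for (int k = 0; k < nz; k++) {
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  }
  // pass along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++) {
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; k++) f[k] = out[base + sz * k];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; k++) out[base + sz * k] = d[k];
    }
  }
  return out;
}
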