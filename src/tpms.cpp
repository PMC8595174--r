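#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Raw sheet-TPMS field f (the expression inside the square of the thresholded
// form U = f^2 - t^2) evaluated on the tensor grid x[i], y[j], z[k]. The
// trigonometric argument is 2*pi*coordinate/cell_size; per-axis sin/cos
// tables make grid evaluation cheap.
//
// type codes: 1 Primitive, 2 Gyroid, 3 Split P, 4 Diamond, 5 Lidinoid,
//             6 Neovius

// [[Rcpp::export(name = ".tpms_field_grid_cpp")]]
NumericVector tpms_field_grid_cpp(int type, NumericVector x, NumericVector y,
                                  NumericVector z, double cell_size) {
  const int nx = x.size(), ny = y.size(), nz = z.size();
  const double w = 2.0 * M_PI / cell_size;
  std::vector<double> Sx(nx), Cx(nx), S2x(nx), C2x(nx);
  std::vector<double> Sy(ny), Cy(ny), S2y(ny), C2y(ny);
  std::vector<double> Sz(nz), Cz(nz), S2z(nz), C2z(nz);
  for (int i = 0; i < nx; i++) {
    Sx[i] = std::sin(w * x[i]); Cx[i] = std::cos(w * x[i]);
    S2x[i] = std::sin(2 * w * x[i]); C2x[i] = std::cos(2 * w * x[i]);
  }
  for (int j = 0; j < ny; j++) {
    Sy[j] = std::sin(w * y[j]); Cy[j] = std::cos(w * y[j]);
    S2y[j] = std::sin(2 * w * y[j]); C2y[j] = std::cos(2 * w * y[j]);
  }
  for (int k = 0; k < nz; k++) {
    Sz[k] = std::sin(w * z[k]); Cz[k] = std::cos(w * z[k]);
    S2z[k] = std::sin(2 * w * z[k]); C2z[k] = std::cos(2 * w * z[k]);
  }

  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t m = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, m++) {
        double f;
        switch (type) {
          case 1:  // Primitive
            f = Cx[i] + Cy[j] + Cz[k];
            break;
          case 2:  // Gyroid
            f = Sx[i] * Cy[j] + Sy[j] * Cz[k] + Sz[k] * Cx[i];
            break;
          case 3:  // Split P
            f = 1.1 * (S2x[i] * Cy[j] * Sz[k] + S2y[j] * Cz[k] * Sx[i] +
                       S2z[k] * Cx[i] * Sy[j]) -
                0.2 * (C2x[i] * C2y[j] + C2y[j] * C2z[k] + C2z[k] * C2x[i]) -
                0.4 * (C2x[i] + C2y[j] + C2z[k]);
            break;
          case 4:  // Diamond
            f = Cx[i] * Cy[j] * Cz[k] + Sx[i] * Sy[j] * Sz[k] +
                Sx[i] * Cy[j] * Sz[k] + Cx[i] * Sy[j] * Sz[k];
            break;
          case 5:  // Lidinoid
            f = (S2x[i] * Cy[j] * Sz[k] + S2y[j] * Cz[k] * Sx[i] +
                 S2z[k] * Cx[i] * Sy[j]) -
                (C2x[i] * C2y[j] + C2y[j] * C2z[k] + C2z[k] * C2x[i]);
            break;
          case 6:  // Neovius
            f = 3.0 * (Cx[i] + Cy[j] + Cz[k]) + 4.0 * Cx[i] * Cy[j] * Cz[k];
            break;
          default:
            stop("unknown TPMS type code");
        }
        out[m] = f;
      }
  return out;
}
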