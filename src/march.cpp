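#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface triangulation by marching tetrahedra: each grid cube is split
// into six tetrahedra sharing the main diagonal, and the zero level of the
// (vertex-sampled) scalar field is triangulated by linear interpolation along
// tetrahedron edges. Shared edges interpolate identically in neighbouring
// tetrahedra, so the mesh is watertight on a closed interface.

static const int TET[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

// cube corner offsets, index 0..7
static const int CO[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                             {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

static inline void interp(const double* pa, const double* pb, double fa,
                          double fb, double* out) {
  double t = fa / (fa - fb);
  for (int d = 0; d < 3; d++) out[d] = pa[d] + t * (pb[d] - pa[d]);
}

// [[Rcpp::export(name = ".march_tets_cpp")]]
NumericMatrix march_tets_cpp(NumericVector field, IntegerVector dim,
                             double spacing, NumericVector origin,
                             double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> tris;
  tris.reserve(1 << 16);
  double P[4][3], f[4], v[4][3];

  for (int z = 0; z < nz - 1; z++)
    for (int y = 0; y < ny - 1; y++)
      for (int x = 0; x < nx - 1; x++) {
        double cf[8];
        double cp[8][3];
        bool all_pos = true, all_neg = true;
        for (int c = 0; c < 8; c++) {
          int xx = x + CO[c][0], yy = y + CO[c][1], zz = z + CO[c][2];
          cf[c] = field[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] - iso;
          cp[c][0] = origin[0] + xx * spacing;
          cp[c][1] = origin[1] + yy * spacing;
          cp[c][2] = origin[2] + zz * spacing;
          if (cf[c] < 0) all_pos = false; else all_neg = false;
        }
        if (all_pos || all_neg) continue;
        for (int t = 0; t < 6; t++) {
          int nin = 0;
          int in_id[4], out_id[4];
          int nout = 0;
          for (int c = 0; c < 4; c++) {
            int cc = TET[t][c];
            f[c] = cf[cc];
            for (int d = 0; d < 3; d++) P[c][d] = cp[cc][d];
            if (f[c] < 0) in_id[nin++] = c; else out_id[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // single separated vertex -> one triangle
            int a = (nin == 1) ? in_id[0] : out_id[0];
            int others[3];
            int m = 0;
            for (int c = 0; c < 4; c++)
              if (c != a) others[m++] = c;
            for (int c = 0; c < 3; c++)
              interp(P[a], P[others[c]], f[a], f[others[c]], v[c]);
            for (int c = 0; c < 3; c++)
              for (int d = 0; d < 3; d++) tris.push_back(v[c][d]);
          } else {
            // 2-2 split -> quad -> two triangles
            int a0 = in_id[0], a1 = in_id[1], b0 = out_id[0], b1 = out_id[1];
            interp(P[a0], P[b0], f[a0], f[b0], v[0]);
            interp(P[a0], P[b1], f[a0], f[b1], v[1]);
            interp(P[a1], P[b1], f[a1], f[b1], v[2]);
            interp(P[a1], P[b0], f[a1], f[b0], v[3]);
            const int q[2][3] = {{0, 1, 2}, {0, 2, 3}};
            for (int tq = 0; tq < 2; tq++)
              for (int c = 0; c < 3; c++)
                for (int d = 0; d < 3; d++) tris.push_back(v[q[tq][c]][d]);
          }
        }
      }

  int ntri = (int)(tris.size() / 9);
  NumericMatrix out(ntri, 9);
  for (int i = 0; i < ntri; i++)
    for (int j = 0; j < 9; j++) out(i, j) = tris[(size_t)i * 9 + j];
  return out;
}
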