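#include <Rcpp.h>
#include <vector>
#include <deque>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Medial-axis skeletonisation of a 3-D binary phase by homotopic thinning:
// simple points (Bertrand/Malandain characterisation, 26-object/6-background
// connectivity pair) are removed in order of increasing Euclidean distance to
// the complement, preserving curve endpoints. The result is a thin,
// topology-preserving medial skeleton (curves in tubular regions, medial
// surfaces where the phase is plate-like).

NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim); // edt.cpp

struct Grid3 {
  int nx, ny, nz;
  R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
  R_xlen_t idx(int x, int y, int z) const {
    return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
  }
  bool in(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// 26-neighbourhood offsets
static int OFF26[26][3];
static bool OFF26_init = false;
static void init_off26() {
  if (OFF26_init) return;
  int m = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFF26[m][0] = dx; OFF26[m][1] = dy; OFF26[m][2] = dz; m++;
      }
  OFF26_init = true;
}

// Gather the 3x3x3 neighbourhood of (x,y,z); out-of-grid cells count as
// background. cube[] is indexed (dx+1) + 3*(dy+1) + 9*(dz+1).
static inline void gather_cube(const std::vector<char>& obj, const Grid3& g,
                               int x, int y, int z, bool cube[27]) {
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int c = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        int xx = x + dx, yy = y + dy, zz = z + dz;
        cube[c] = g.in(xx, yy, zz) ? (obj[g.idx(xx, yy, zz)] != 0) : false;
      }
}

static inline int cube_c(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of object voxels in the 26-neighbourhood
static inline int count26(const bool cube[27]) {
  int c = 0;
  for (int i = 0; i < 27; i++) if (i != 13 && cube[i]) c++;
  return c;
}

// C*: number of 26-connected components of the object within N26*(v)
static int object_components26(const bool cube[27]) {
  int label[27];
  for (int i = 0; i < 27; i++) label[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; s++) {
    if (s == 13 || !cube[s] || label[s] >= 0) continue;
    ncomp++;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int c2 = x + 3 * y + 9 * z;
            if (c2 == c || c2 == 13 || !cube[c2] || label[c2] >= 0) continue;
            label[c2] = ncomp;
            stack[top++] = c2;
          }
    }
  }
  return ncomp;
}

// Cbar: number of 6-connected components of the background restricted to the
// 18-neighbourhood that touch a face neighbour of v.
static int background_components6(const bool cube[27]) {
  // membership in N18: |dx|+|dy|+|dz| <= 2 (corners excluded), not the centre
  bool inN18[27];
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int c = cube_c(dx, dy, dz);
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        inN18[c] = (m >= 1 && m <= 2);
      }
  int label[27];
  for (int i = 0; i < 27; i++) label[i] = -1;
  int ncomp = 0;
  for (int s = 0; s < 27; s++) {
    if (!inN18[s] || cube[s] || label[s] >= 0) continue;
    // flood over 6-adjacency within N18 background
    int comp = ++ncomp;
    bool touches_face = false;
    int stack[27];
    int top = 0;
    stack[top++] = s;
    label[s] = comp;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      if (std::abs(cx) + std::abs(cy) + std::abs(cz) == 1) touches_face = true;
      static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int f = 0; f < 6; f++) {
        int x = cx + F[f][0], y = cy + F[f][1], z = cz + F[f][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        int c2 = cube_c(x, y, z);
        if (!inN18[c2] || cube[c2] || label[c2] >= 0) continue;
        label[c2] = comp;
        stack[top++] = c2;
      }
    }
    if (!touches_face) ncomp--; // component not 6-adjacent to v: ignore
  }
  return ncomp;
}

static inline bool is_simple(const bool cube[27]) {
  return object_components26(cube) == 1 && background_components6(cube) == 1;
}

// one distance-ordered homotopic erosion pass; anchors (if any) are never
// removed, curve endpoints are preserved
static void thin_pass(std::vector<char>& obj, const Grid3& g,
                      const NumericVector& d2, const std::vector<char>* anchor) {
  const R_xlen_t n = g.n();
  double maxd = 0;
  for (R_xlen_t i = 0; i < n; i++)
    if (obj[i] && d2[i] < 1e29 && d2[i] > maxd) maxd = d2[i];
  int nbuck = (int)std::llround(maxd) + 2;
  std::vector<std::deque<R_xlen_t> > bucket(nbuck);
  std::vector<char> queued(n, 0);

  bool cube[27];
  for (int z = 0; z < g.nz; z++)
    for (int y = 0; y < g.ny; y++)
      for (int x = 0; x < g.nx; x++) {
        R_xlen_t i = g.idx(x, y, z);
        if (!obj[i]) continue;
        bool border = false;
        for (int m = 0; m < 26 && !border; m++) {
          int xx = x + OFF26[m][0], yy = y + OFF26[m][1], zz = z + OFF26[m][2];
          if (!g.in(xx, yy, zz) || !obj[g.idx(xx, yy, zz)]) border = true;
        }
        if (border) {
          int key = (int)std::llround(std::min(d2[i], maxd));
          bucket[key].push_back(i);
          queued[i] = 1;
        }
      }

  int cur = 0;
  while (cur < nbuck) {
    if (bucket[cur].empty()) { cur++; continue; }
    R_xlen_t i = bucket[cur].front();
    bucket[cur].pop_front();
    queued[i] = 0;
    if (!obj[i]) continue;
    if (anchor && (*anchor)[i]) continue;
    int x = (int)(i % g.nx), y = (int)((i / g.nx) % g.ny), z = (int)(i / ((R_xlen_t)g.nx * g.ny));
    gather_cube(obj, g, x, y, z, cube);
    if (count26(cube) <= 1) continue;  // curve endpoint: preserve
    if (!is_simple(cube)) continue;
    obj[i] = 0;                        // remove
    for (int m = 0; m < 26; m++) {
      int xx = x + OFF26[m][0], yy = y + OFF26[m][1], zz = z + OFF26[m][2];
      if (!g.in(xx, yy, zz)) continue;
      R_xlen_t j = g.idx(xx, yy, zz);
      if (obj[j] && !queued[j]) {
        int key = (int)std::llround(std::min((double)d2[j], maxd));
        bucket[key].push_back(j);
        queued[j] = 1;
        if (key < cur) cur = key;
      }
    }
  }
}

// [[Rcpp::export(name = ".thin_skeleton_cpp")]]
LogicalVector thin_skeleton_cpp(LogicalVector object, IntegerVector dim) {
  init_off26();
  Grid3 g{dim[0], dim[1], dim[2]};
  const R_xlen_t n = g.n();
  if (object.size() != n) stop("object length does not match dim");
  std::vector<char> obj(n);
  for (R_xlen_t i = 0; i < n; i++) obj[i] = object[i] ? 1 : 0;

  NumericVector d2 = edt_sq_cpp(!object, dim); // squared distance to background

  // anchor the plateau-inclusive local maxima of the distance transform:
  // these pin the skeleton to the distance ridge, which stops topologically
  // trivial tubes being eroded away from their open ends (looped channels
  // are already protected by the homotopy-preserving removal rule).
  std::vector<char> anchor(n, 0);
  for (int z = 0; z < g.nz; z++)
    for (int y = 0; y < g.ny; y++)
      for (int x = 0; x < g.nx; x++) {
        R_xlen_t i = g.idx(x, y, z);
        if (!obj[i]) continue;
        bool dominated = false;
        for (int m = 0; m < 26 && !dominated; m++) {
          int xx = x + OFF26[m][0], yy = y + OFF26[m][1], zz = z + OFF26[m][2];
          if (!g.in(xx, yy, zz)) continue;
          R_xlen_t j = g.idx(xx, yy, zz);
          if (obj[j] && d2[j] > d2[i]) dominated = true;
        }
        if (!dominated) anchor[i] = 1;
      }

  thin_pass(obj, g, d2, &anchor);   // erode to the anchored medial set

  // de-thicken anchor plateaus: degenerate grid alignments leave 2-voxel
  // thick medial plateaus; remove simple non-endpoint voxels that take part
  // in a fully occupied 2x2x2 block (lowest-distance voxel first) until no
  // such block remains
  bool changed = true;
  bool cube[27];
  while (changed) {
    changed = false;
    for (int z = 0; z + 1 < g.nz; z++)
      for (int y = 0; y + 1 < g.ny; y++)
        for (int x = 0; x + 1 < g.nx; x++) {
          bool full = true;
          R_xlen_t blk[8];
          int m = 0;
          for (int dz = 0; dz < 2 && full; dz++)
            for (int dy = 0; dy < 2 && full; dy++)
              for (int dx = 0; dx < 2; dx++) {
                R_xlen_t i = g.idx(x + dx, y + dy, z + dz);
                blk[m++] = i;
                if (!obj[i]) { full = false; break; }
              }
          if (!full) continue;
          // candidates ordered by increasing distance
          for (int pass = 0; pass < 8; pass++) {
            int best = -1;
            double bestd = 1e300;
            for (int c = 0; c < 8; c++) {
              if (blk[c] < 0 || !obj[blk[c]]) continue;
              if (d2[blk[c]] < bestd) { bestd = d2[blk[c]]; best = c; }
            }
            if (best < 0) break;
            R_xlen_t i = blk[best];
            blk[best] = -1;  // do not retry this one
            int bx = (int)(i % g.nx), by = (int)((i / g.nx) % g.ny),
                bz = (int)(i / ((R_xlen_t)g.nx * g.ny));
            gather_cube(obj, g, bx, by, bz, cube);
            if (count26(cube) <= 1 || !is_simple(cube)) continue;
            obj[i] = 0;
            changed = true;
            break;
          }
        }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = obj[i] != 0;
  return out;
}

// Largest connected component of a binary mask (conn = 6 or 26).
// [[Rcpp::export(name = ".largest_component_cpp")]]
LogicalVector largest_component_cpp(LogicalVector mask, IntegerVector dim,
                                    int conn) {
  init_off26();
  Grid3 g{dim[0], dim[1], dim[2]};
  const R_xlen_t n = g.n();
  std::vector<int> label(n, 0);
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best = 0;
  static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || label[s]) continue;
    int comp = ++ncomp;
    R_xlen_t size = 0;
    std::deque<R_xlen_t> q;
    q.push_back(s);
    label[s] = comp;
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop_front();
      size++;
      int x = (int)(i % g.nx), y = (int)((i / g.nx) % g.ny), z = (int)(i / ((R_xlen_t)g.nx * g.ny));
      int nn = (conn == 6) ? 6 : 26;
      for (int m = 0; m < nn; m++) {
        int dx, dy, dz;
        if (conn == 6) { dx = F6[m][0]; dy = F6[m][1]; dz = F6[m][2]; }
        else { dx = OFF26[m][0]; dy = OFF26[m][1]; dz = OFF26[m][2]; }
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (!g.in(xx, yy, zz)) continue;
        R_xlen_t j = g.idx(xx, yy, zz);
        if (mask[j] && !label[j]) { label[j] = comp; q.push_back(j); }
      }
    }
    if (size > best_size) { best_size = size; best = comp; }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = (label[i] == best && best > 0);
  return out;
}

// Count connected components of a mask.
// [[Rcpp::export(name = ".count_components_cpp")]]
int count_components_cpp(LogicalVector mask, IntegerVector dim, int conn) {
  init_off26();
  Grid3 g{dim[0], dim[1], dim[2]};
  const R_xlen_t n = g.n();
  std::vector<char> seen(n, 0);
  int ncomp = 0;
  static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || seen[s]) continue;
    ncomp++;
    std::deque<R_xlen_t> q;
    q.push_back(s);
    seen[s] = 1;
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop_front();
      int x = (int)(i % g.nx), y = (int)((i / g.nx) % g.ny), z = (int)(i / ((R_xlen_t)g.nx * g.ny));
      int nn = (conn == 6) ? 6 : 26;
      for (int m = 0; m < nn; m++) {
        int dx, dy, dz;
        if (conn == 6) { dx = F6[m][0]; dy = F6[m][1]; dz = F6[m][2]; }
        else { dx = OFF26[m][0]; dy = OFF26[m][1]; dz = OFF26[m][2]; }
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (!g.in(xx, yy, zz)) continue;
        R_xlen_t j = g.idx(xx, yy, zz);
        if (mask[j] && !seen[j]) { seen[j] = 1; q.push_back(j); }
      }
    }
  }
  return ncomp;
}

// Integer labels of connected components (0 = background).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int conn) {
  init_off26();
  Grid3 g{dim[0], dim[1], dim[2]};
  const R_xlen_t n = g.n();
  IntegerVector label(n);
  int ncomp = 0;
  static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || label[s]) continue;
    int comp = ++ncomp;
    std::deque<R_xlen_t> q;
    q.push_back(s);
    label[s] = comp;
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop_front();
      int x = (int)(i % g.nx), y = (int)((i / g.nx) % g.ny), z = (int)(i / ((R_xlen_t)g.nx * g.ny));
      int nn = (conn == 6) ? 6 : 26;
      for (int m = 0; m < nn; m++) {
        int dx, dy, dz;
        if (conn == 6) { dx = F6[m][0]; dy = F6[m][1]; dz = F6[m][2]; }
        else { dx = OFF26[m][0]; dy = OFF26[m][1]; dz = OFF26[m][2]; }
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (!g.in(xx, yy, zz)) continue;
        R_xlen_t j = g.idx(xx, yy, zz);
        if (mask[j] && !label[j]) { label[j] = comp; q.push_back(j); }
      }
    }
  }
  return label;
}

// Prune short terminal branches (< min_branch voxels up to the first junction)
// from a skeleton mask. Single sweep over all leaves.
// [[Rcpp::export(name = ".prune_skeleton_cpp")]]
LogicalVector prune_skeleton_cpp(LogicalVector skel, IntegerVector dim,
                                 int min_branch) {
  init_off26();
  Grid3 g{dim[0], dim[1], dim[2]};
  const R_xlen_t n = g.n();
  std::vector<char> s(n);
  for (R_xlen_t i = 0; i < n; i++) s[i] = skel[i] ? 1 : 0;

  auto degree = [&](R_xlen_t i) {
    int x = (int)(i % g.nx), y = (int)((i / g.nx) % g.ny), z = (int)(i / ((R_xlen_t)g.nx * g.ny));
    int d = 0;
    for (int m = 0; m < 26; m++) {
      int xx = x + OFF26[m][0], yy = y + OFF26[m][1], zz = z + OFF26[m][2];
      if (g.in(xx, yy, zz) && s[g.idx(xx, yy, zz)]) d++;
    }
    return d;
  };
  auto neighbours = [&](R_xlen_t i, std::vector<R_xlen_t>& nb) {
    nb.clear();
    int x = (int)(i % g.nx), y = (int)((i / g.nx) % g.ny), z = (int)(i / ((R_xlen_t)g.nx * g.ny));
    for (int m = 0; m < 26; m++) {
      int xx = x + OFF26[m][0], yy = y + OFF26[m][1], zz = z + OFF26[m][2];
      if (g.in(xx, yy, zz) && s[g.idx(xx, yy, zz)]) nb.push_back(g.idx(xx, yy, zz));
    }
  };

  std::vector<R_xlen_t> leaves, nb, chain;
  for (R_xlen_t i = 0; i < n; i++)
    if (s[i] && degree(i) == 1) leaves.push_back(i);

  for (size_t L = 0; L < leaves.size(); L++) {
    R_xlen_t v = leaves[L];
    if (!s[v]) continue;
    chain.clear();
    R_xlen_t prev = -1;
    bool hit_junction = false;
    while (true) {
      chain.push_back(v);
      if ((int)chain.size() >= min_branch) break; // long enough: keep
      neighbours(v, nb);
      R_xlen_t next = -1;
      int others = 0;
      for (size_t m = 0; m < nb.size(); m++)
        if (nb[m] != prev) { others++; next = nb[m]; }
      if (others == 0) break;              // isolated short chain: keep as is
      if (others > 1) { hit_junction = false; break; }
      // does next continue a simple chain, or is it a junction?
      if (degree(next) > 2) { hit_junction = true; break; }
      prev = v;
      v = next;
      if (degree(v) > 2) { hit_junction = true; chain.pop_back(); break; }
    }
    if (hit_junction && (int)chain.size() < min_branch)
      for (size_t m = 0; m < chain.size(); m++) s[chain[m]] = 0;
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = s[i] != 0;
  return out;
}
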