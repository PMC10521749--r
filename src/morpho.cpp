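// Volumetric morphometry kernels: 26-connected component labelling,
// separable Gaussian smoothing, marching-tetrahedra isosurface area.
// Arrays follow the package convention dim = (nz, ny, nx), z fastest.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".cc_largest")]]
LogicalVector cc_largest(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  std::vector<int> lab(n, 0);
  int next = 0, best = 0, bestCount = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
    int i0 = idx3(z, y, x, nz, ny);
    if (!mask[i0] || lab[i0]) continue;
    ++next;
    int count = 0;
    stack.clear(); stack.push_back(i0); lab[i0] = next;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back(); ++count;
      int cz = i % nz, rest = i / nz, cy = rest % ny, cx = rest / ny;
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int zz = cz + dz, yy = cy + dy, xx = cx + dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int j = idx3(zz, yy, xx, nz, ny);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
    if (count > bestCount) { bestCount = count; best = next; }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (lab[i] == best) && best > 0;
  out.attr("dim") = dims;
  return out;
}

static void smooth_axis(std::vector<double> &v, int nz, int ny, int nx,
                        int axis, const std::vector<double> &k) {
  const int r = ((int)k.size() - 1) / 2;
  const int len[3] = {nz, ny, nx};
  const int n = nz * ny * nx;
  std::vector<double> out(n);
  const int stride[3] = {1, nz, nz * ny};
  const int L = len[axis], S = stride[axis];
  // iterate over all lines along `axis`
  for (int x = 0; x < (axis == 2 ? 1 : nx); ++x)
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
      for (int z = 0; z < (axis == 0 ? 1 : nz); ++z) {
        int base = idx3(z, y, x, nz, ny);
        for (int t = 0; t < L; ++t) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int tt = t + j;
            if (tt < 0) tt = -tt - 1;          // reflect
            if (tt >= L) tt = 2 * L - tt - 1;
            acc += k[j + r] * v[base + tt * S];
          }
          out[base + t * S] = acc;
        }
      }
  v.swap(out);
}

// [[Rcpp::export(name = ".gaussian_smooth3d")]]
NumericVector gaussian_smooth3d(NumericVector vol, IntegerVector dims, double sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  std::vector<double> v(vol.begin(), vol.end());
  if (sigma > 0) {
    int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> k(2 * r + 1);
    double s = 0;
    for (int j = -r; j <= r; ++j) { k[j + r] = std::exp(-0.5 * j * j / (sigma * sigma)); s += k[j + r]; }
    for (double &kk : k) kk /= s;
    for (int ax = 0; ax < 3; ++ax) smooth_axis(v, nz, ny, nx, ax, k);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// Marching tetrahedra over the trilinear lattice: each cell is split into 6
// tetrahedra sharing the main diagonal; triangle vertices are linear
// interpolations along tet edges at `iso`. Returns total area in physical
// units given anisotropic pitch (pz, py, px).
struct P3 { double x, y, z; };

static inline P3 lerp(const P3 &a, const P3 &b, double va, double vb, double iso) {
  double t = (iso - va) / (vb - va);
  P3 p; p.x = a.x + t * (b.x - a.x); p.y = a.y + t * (b.y - a.y); p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline double triArea(const P3 &a, const P3 &b, const P3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export(name = ".isosurface_area")]]
double isosurface_area(NumericVector vol, IntegerVector dims, double iso,
                       NumericVector pitch) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double pz = pitch[0], py = pitch[1], px = pitch[2];
  // cube corner offsets in (x, y, z)
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double area = 0.0;
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        double cv[8]; P3 cp[8];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + co[c][0], yy = y + co[c][1], zz = z + co[c][2];
          cv[c] = vol[idx3(zz, yy, xx, nz, ny)];
          cp[c].x = xx * px; cp[c].y = yy * py; cp[c].z = zz * pz;
          (cv[c] > iso ? anyIn : anyOut) = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int inMask = 0;
          for (int c = 0; c < 4; ++c) if (cv[T[c]] > iso) inMask |= (1 << c);
          if (inMask == 0 || inMask == 15) continue;
          int nin = __builtin_popcount(inMask);
          int ins[4], outs[4]; int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) (inMask & (1 << c)) ? ins[ni++] = T[c] : outs[no++] = T[c];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            const int *ring = (nin == 1) ? outs : ins;
            P3 e0 = lerp(cp[apex], cp[ring[0]], cv[apex], cv[ring[0]], iso);
            P3 e1 = lerp(cp[apex], cp[ring[1]], cv[apex], cv[ring[1]], iso);
            P3 e2 = lerp(cp[apex], cp[ring[2]], cv[apex], cv[ring[2]], iso);
            area += triArea(e0, e1, e2);
          } else { // 2 in, 2 out -> quad
            P3 e00 = lerp(cp[ins[0]], cp[outs[0]], cv[ins[0]], cv[outs[0]], iso);
            P3 e01 = lerp(cp[ins[0]], cp[outs[1]], cv[ins[0]], cv[outs[1]], iso);
            P3 e10 = lerp(cp[ins[1]], cp[outs[0]], cv[ins[1]], cv[outs[0]], iso);
            P3 e11 = lerp(cp[ins[1]], cp[outs[1]], cv[ins[1]], cv[outs[1]], iso);
            area += triArea(e00, e01, e11) + triArea(e00, e11, e10);
          }
        }
      }
  return area;
}
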