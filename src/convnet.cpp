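// Dense volumetric conv-net kernels: same-padded 3D convolution (direct
// shifted-accumulate form, contiguous along z), max pooling with cached
// argmax, nearest-neighbour upsampling. Activations are column-major
// arrays dim (nz, ny, nx, C, N), z fastest; 2D images are handled as
// nz == 1 with kernel/pool extent 1 along z.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector input, IntegerVector dims,
                       NumericVector weight, IntegerVector kdims,
                       NumericVector bias) {
  const int nz = dims[0], ny = dims[1], nx = dims[2], cin = dims[3], N = dims[4];
  const int kz = kdims[0], ky = kdims[1], kx = kdims[2], cout = kdims[4];
  const int pz = (kz - 1) / 2, py = (ky - 1) / 2, px = (kx - 1) / 2;
  const size_t nvox = (size_t)nz * ny * nx;
  const int K = kz * ky * kx;
  NumericVector out((R_xlen_t)(nvox * cout * N));
  const double *W = weight.begin();
  for (int s = 0; s < N; ++s) {
    const double *in = input.begin() + (size_t)s * nvox * cin;
    double *o0 = out.begin() + (size_t)s * nvox * cout;
    for (int co = 0; co < cout; ++co) {
      double *oc = o0 + (size_t)co * nvox;
      const double bco = bias[co];
      for (size_t i = 0; i < nvox; ++i) oc[i] = bco;
      for (int ci = 0; ci < cin; ++ci) {
        const double *ic = in + (size_t)ci * nvox;
        for (int dx = 0; dx < kx; ++dx)
          for (int dy = 0; dy < ky; ++dy)
            for (int dz = 0; dz < kz; ++dz) {
              const double w = W[dz + kz * (dy + ky * (dx + kx * (ci + (size_t)cin * co)))];
              if (w == 0.0) continue;
              const int sx0 = dx - px, sy0 = dy - py, sz0 = dz - pz;
              const int xlo = std::max(0, -sx0), xhi = std::min(nx, nx - sx0);
              const int ylo = std::max(0, -sy0), yhi = std::min(ny, ny - sy0);
              const int zlo = std::max(0, -sz0), zhi = std::min(nz, nz - sz0);
              for (int x = xlo; x < xhi; ++x)
                for (int y = ylo; y < yhi; ++y) {
                  double *op = oc + ((size_t)x * ny + y) * nz + zlo;
                  const double *ip = ic + ((size_t)(x + sx0) * ny + (y + sy0)) * nz + zlo + sz0;
                  const int len = zhi - zlo;
                  for (int z = 0; z < len; ++z) op[z] += w * ip[z];
                }
            }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx, cout, N);
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector input, IntegerVector dims,
              NumericVector weight, IntegerVector kdims,
              NumericVector gradOut) {
  const int nz = dims[0], ny = dims[1], nx = dims[2], cin = dims[3], N = dims[4];
  const int kz = kdims[0], ky = kdims[1], kx = kdims[2], cout = kdims[4];
  const int pz = (kz - 1) / 2, py = (ky - 1) / 2, px = (kx - 1) / 2;
  const size_t nvox = (size_t)nz * ny * nx;
  NumericVector gradIn((R_xlen_t)(nvox * cin * N));
  NumericVector dW((R_xlen_t)weight.size());
  NumericVector db(cout);
  const double *W = weight.begin();
  for (int s = 0; s < N; ++s) {
    const double *in = input.begin() + (size_t)s * nvox * cin;
    const double *go = gradOut.begin() + (size_t)s * nvox * cout;
    double *gi = gradIn.begin() + (size_t)s * nvox * cin;
    for (int co = 0; co < cout; ++co) {
      const double *gc = go + (size_t)co * nvox;
      double acc = 0.0;
      for (size_t i = 0; i < nvox; ++i) acc += gc[i];
      db[co] += acc;
      for (int ci = 0; ci < cin; ++ci) {
        const double *ic = in + (size_t)ci * nvox;
        double *gic = gi + (size_t)ci * nvox;
        for (int dx = 0; dx < kx; ++dx)
          for (int dy = 0; dy < ky; ++dy)
            for (int dz = 0; dz < kz; ++dz) {
              const size_t wi = dz + kz * (dy + ky * (dx + kx * (ci + (size_t)cin * co)));
              const double w = W[wi];
              const int sx0 = dx - px, sy0 = dy - py, sz0 = dz - pz;
              const int xlo = std::max(0, -sx0), xhi = std::min(nx, nx - sx0);
              const int ylo = std::max(0, -sy0), yhi = std::min(ny, ny - sy0);
              const int zlo = std::max(0, -sz0), zhi = std::min(nz, nz - sz0);
              const int len = zhi - zlo;
              double dw = 0.0;
              for (int x = xlo; x < xhi; ++x)
                for (int y = ylo; y < yhi; ++y) {
                  const double *gp = gc + ((size_t)x * ny + y) * nz + zlo;
                  const double *ip = ic + ((size_t)(x + sx0) * ny + (y + sy0)) * nz + zlo + sz0;
                  double *gip = gic + ((size_t)(x + sx0) * ny + (y + sy0)) * nz + zlo + sz0;
                  for (int z = 0; z < len; ++z) {
                    dw += gp[z] * ip[z];
                    gip[z] += w * gp[z];
                  }
                }
              dW[wi] += dw;
            }
      }
    }
  }
  gradIn.attr("dim") = dims;
  dW.attr("dim") = kdims;
  return List::create(_["gradIn"] = gradIn, _["gradW"] = dW,
                      _["gradB"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector input, IntegerVector dims, IntegerVector pool) {
  const int nz = dims[0], ny = dims[1], nx = dims[2], C = dims[3], N = dims[4];
  const int fz = pool[0], fy = pool[1], fx = pool[2];
  const int oz = nz / fz, oy = ny / fy, ox = nx / fx;
  const size_t onvox = (size_t)oz * oy * ox, invox = (size_t)nz * ny * nx;
  NumericVector out((R_xlen_t)(onvox * C * N));
  IntegerVector arg((R_xlen_t)(onvox * C * N));
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double *in = input.begin() + ((size_t)s * C + c) * invox;
      double *o = out.begin() + ((size_t)s * C + c) * onvox;
      int *a = arg.begin() + ((size_t)s * C + c) * onvox;
      for (int x = 0; x < ox; ++x)
        for (int y = 0; y < oy; ++y)
          for (int z = 0; z < oz; ++z) {
            double best = -1e300; int bi = -1;
            for (int dx = 0; dx < fx; ++dx)
              for (int dy = 0; dy < fy; ++dy)
                for (int dz = 0; dz < fz; ++dz) {
                  int i = (z * fz + dz) + nz * ((y * fy + dy) + (size_t)ny * (x * fx + dx));
                  if (in[i] > best) { best = in[i]; bi = i; }
                }
            o[z + oz * (y + (size_t)oy * x)] = best;
            a[z + oz * (y + (size_t)oy * x)] = bi;
          }
    }
  out.attr("dim") = IntegerVector::create(oz, oy, ox, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector gradOut, IntegerVector argmax,
                          IntegerVector inDims, IntegerVector outDims) {
  const size_t invox = (size_t)inDims[0] * inDims[1] * inDims[2];
  const size_t onvox = (size_t)outDims[0] * outDims[1] * outDims[2];
  const int C = inDims[3], N = inDims[4];
  NumericVector gradIn((R_xlen_t)(invox * C * N));
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double *go = gradOut.begin() + ((size_t)s * C + c) * onvox;
      const int *a = argmax.begin() + ((size_t)s * C + c) * onvox;
      double *gi = gradIn.begin() + ((size_t)s * C + c) * invox;
      for (size_t i = 0; i < onvox; ++i) gi[a[i]] += go[i];
    }
  gradIn.attr("dim") = inDims;
  return gradIn;
}

// [[Rcpp::export(name = ".upsample_fwd")]]
NumericVector upsample_fwd(NumericVector input, IntegerVector dims, IntegerVector fac) {
  const int nz = dims[0], ny = dims[1], nx = dims[2], C = dims[3], N = dims[4];
  const int fz = fac[0], fy = fac[1], fx = fac[2];
  const int oz = nz * fz, oy = ny * fy, ox = nx * fx;
  const size_t invox = (size_t)nz * ny * nx, onvox = (size_t)oz * oy * ox;
  NumericVector out((R_xlen_t)(onvox * C * N));
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double *in = input.begin() + ((size_t)s * C + c) * invox;
      double *o = out.begin() + ((size_t)s * C + c) * onvox;
      for (int x = 0; x < ox; ++x)
        for (int y = 0; y < oy; ++y) {
          const double *ip = in + ((size_t)(x / fx) * ny + (y / fy)) * nz;
          double *op = o + ((size_t)x * oy + y) * oz;
          for (int z = 0; z < oz; ++z) op[z] = ip[z / fz];
        }
    }
  out.attr("dim") = IntegerVector::create(oz, oy, ox, C, N);
  return out;
}

// [[Rcpp::export(name = ".upsample_bwd")]]
NumericVector upsample_bwd(NumericVector gradOut, IntegerVector inDims, IntegerVector fac) {
  const int nz = inDims[0], ny = inDims[1], nx = inDims[2], C = inDims[3], N = inDims[4];
  const int fz = fac[0], fy = fac[1], fx = fac[2];
  const int oz = nz * fz, oy = ny * fy, ox = nx * fx;
  const size_t invox = (size_t)nz * ny * nx, onvox = (size_t)oz * oy * ox;
  NumericVector gradIn((R_xlen_t)(invox * C * N));
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double *go = gradOut.begin() + ((size_t)s * C + c) * onvox;
      double *gi = gradIn.begin() + ((size_t)s * C + c) * invox;
      for (int x = 0; x < ox; ++x)
        for (int y = 0; y < oy; ++y) {
          const double *gp = go + ((size_t)x * oy + y) * oz;
          double *gip = gi + ((size_t)(x / fx) * ny + (y / fy)) * nz;
          for (int z = 0; z < oz; ++z) gip[z / fz] += gp[z];
        }
    }
  gradIn.attr("dim") = inDims;
  return gradIn;
}
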