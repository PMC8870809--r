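#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Affine resampling of a 3D scalar field.
// For output voxel (0-based) index o, the source continuous 0-based index is
// s = A %*% o + b.  Trilinear or nearest-neighbour; source coordinates outside
// [-0.5, n-0.5) map to `fill`.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector in_dim,
                                  IntegerVector out_dim, NumericMatrix A,
                                  NumericVector b, bool linear, double fill) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i) {
        double sx = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
        double sy = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
        double sz = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
        double val;
        if (linear) {
          if (sx < -0.5 || sy < -0.5 || sz < -0.5 ||
              sx > nx - 0.5 || sy > ny - 0.5 || sz > nz - 0.5) {
            val = fill;
          } else {
            int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
            double fx = sx - x0, fy = sy - y0, fz = sz - z0;
            val = 0.0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy2 = 0; dy2 <= 1; ++dy2)
                for (int dx = 0; dx <= 1; ++dx) {
                  int xi = x0 + dx, yi = y0 + dy2, zi = z0 + dz;
                  double w = (dx ? fx : 1 - fx) * (dy2 ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                  if (w == 0.0) continue;
                  double src;
                  if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
                    src = fill;  // clamp half-voxel border to fill
                  else
                    src = v[vidx(xi, yi, zi, nx, ny)];
                  val += w * src;
                }
          }
        } else {
          int xi = (int)std::lround(sx), yi = (int)std::lround(sy), zi = (int)std::lround(sz);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
            val = fill;
          else
            val = v[vidx(xi, yi, zi, nx, ny)];
        }
        o[vidx(i, j, k, ox, oy)] = val;
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing, sigma in voxels, truncated at 3 sigma.
// Borders renormalise over the in-field part of the kernel.
// [[Rcpp::export]]
NumericVector gaussian_smooth_cpp(NumericVector vol, IntegerVector dim, double sigma) {
  if (sigma <= 0) return clone(vol);
  const int n[3] = {dim[0], dim[1], dim[2]};
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t)
    kern[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
  NumericVector cur = clone(vol);
  NumericVector nxt((R_xlen_t)n[0] * n[1] * n[2]);
  for (int axis = 0; axis < 3; ++axis) {
    for (int k = 0; k < n[2]; ++k)
      for (int j = 0; j < n[1]; ++j)
        for (int i = 0; i < n[0]; ++i) {
          double acc = 0, wsum = 0;
          for (int t = -rad; t <= rad; ++t) {
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii += t; else if (axis == 1) jj += t; else kk += t;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n[0] || jj >= n[1] || kk >= n[2]) continue;
            double w = kern[t + rad];
            acc += w * cur[vidx(ii, jj, kk, n[0], n[1])];
            wsum += w;
          }
          nxt[vidx(i, j, k, n[0], n[1])] = acc / wsum;
        }
    std::swap(cur, nxt);
  }
  return cur;
}
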