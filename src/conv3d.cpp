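// 3D convolution primitives for the V-NET module.
// Volumes are R arrays with dim (X, Y, Z, C): each channel is a contiguous
// column-major block.  Convolution weights are matrices (Cout, Cin*k^3) with
// row index r = cin*k^3 + (dx + k*(dy + k*dz)); forward/backward passes use
// im2col + GEMM.  The 2x2x2 stride-2 transposed convolution (used for the
// decoder upsampling) is written directly: its output taps never overlap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outdim(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

static arma::mat im2col3(const double *x, int X, int Y, int Z, int Cin,
                         int k, int s, int p, int OX, int OY, int OZ) {
  const arma::uword k3 = (arma::uword)k * k * k;
  const arma::uword Nout = (arma::uword)OX * OY * OZ;
  arma::mat col((arma::uword)Cin * k3, Nout);
  const R_xlen_t chan = (R_xlen_t)X * Y * Z;
  for (int oz = 0; oz < OZ; ++oz)
    for (int oy = 0; oy < OY; ++oy)
      for (int ox = 0; ox < OX; ++ox) {
        arma::uword n = (arma::uword)ox + (arma::uword)OX * (oy + (arma::uword)OY * oz);
        double *dst = col.colptr(n);
        for (int c = 0; c < Cin; ++c) {
          const double *xc = x + (R_xlen_t)c * chan;
          for (int dz = 0; dz < k; ++dz) {
            int zi = oz * s - p + dz;
            for (int dy = 0; dy < k; ++dy) {
              int yi = oy * s - p + dy;
              for (int dx = 0; dx < k; ++dx) {
                int xi = ox * s - p + dx;
                arma::uword r = (arma::uword)c * k3 + (dx + k * (dy + k * dz));
                if (xi < 0 || yi < 0 || zi < 0 || xi >= X || yi >= Y || zi >= Z)
                  dst[r] = 0.0;
                else
                  dst[r] = xc[(R_xlen_t)xi + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi)];
              }
            }
          }
        }
      }
  return col;
}

// [[Rcpp::export]]
List conv3d_fwd_cpp(NumericVector x, IntegerVector dim, int cin,
                    const arma::mat &W, const arma::vec &bias,
                    int k, int stride, int pad, bool keep_col) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const int OX = outdim(X, k, stride, pad), OY = outdim(Y, k, stride, pad),
            OZ = outdim(Z, k, stride, pad);
  arma::mat col = im2col3(x.begin(), X, Y, Z, cin, k, stride, pad, OX, OY, OZ);
  arma::mat Yt = col.t() * W.t();           // (Nout, Cout), contiguous per channel
  Yt.each_row() += bias.t();
  NumericVector out(Yt.begin(), Yt.end());
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, (int)W.n_rows);
  if (keep_col) return List::create(_["y"] = out, _["col"] = col);
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector dy, const arma::mat &col, const arma::mat &W,
                    IntegerVector in_dim, int cin, int k, int stride, int pad) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2];
  const int OX = outdim(X, k, stride, pad), OY = outdim(Y, k, stride, pad),
            OZ = outdim(Z, k, stride, pad);
  const arma::uword Nout = (arma::uword)OX * OY * OZ;
  const arma::uword Cout = W.n_rows;
  arma::mat dYt(dy.begin(), Nout, Cout, false);   // (Nout, Cout) view
  arma::mat dW = dYt.t() * col.t();               // (Cout, Cin*k^3)
  arma::vec db = arma::sum(dYt, 0).t();
  arma::mat dcol = W.t() * dYt.t();               // (Cin*k^3, Nout)
  const arma::uword k3 = (arma::uword)k * k * k;
  NumericVector dx((R_xlen_t)X * Y * Z * cin);
  double *dxp = dx.begin();
  const R_xlen_t chan = (R_xlen_t)X * Y * Z;
  for (int oz = 0; oz < OZ; ++oz)
    for (int oy = 0; oy < OY; ++oy)
      for (int ox = 0; ox < OX; ++ox) {
        arma::uword n = (arma::uword)ox + (arma::uword)OX * (oy + (arma::uword)OY * oz);
        const double *src = dcol.colptr(n);
        for (int c = 0; c < cin; ++c) {
          double *dc = dxp + (R_xlen_t)c * chan;
          for (int dz = 0; dz < k; ++dz) {
            int zi = oz * stride - pad + dz;
            if (zi < 0 || zi >= Z) continue;
            for (int dyk = 0; dyk < k; ++dyk) {
              int yi = oy * stride - pad + dyk;
              if (yi < 0 || yi >= Y) continue;
              for (int dxk = 0; dxk < k; ++dxk) {
                int xi = ox * stride - pad + dxk;
                if (xi < 0 || xi >= X) continue;
                dc[(R_xlen_t)xi + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi)] +=
                  src[(arma::uword)c * k3 + (dxk + k * (dyk + k * dz))];
              }
            }
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, cin);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
// W is (Cout, Cin*8) with row index r = cin*8 + (dx + 2*(dy + 2*dz)).
// [[Rcpp::export]]
NumericVector upconv3d_fwd_cpp(NumericVector x, IntegerVector dim, int cin,
                               const arma::mat &W, const arma::vec &bias) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const int OX = 2 * X, OY = 2 * Y, OZ = 2 * Z;
  const int Cout = W.n_rows;
  NumericVector out((R_xlen_t)OX * OY * OZ * Cout);
  double *op = out.begin();
  const double *xp = x.begin();
  const R_xlen_t chan_in = (R_xlen_t)X * Y * Z, chan_out = (R_xlen_t)OX * OY * OZ;
  for (int co = 0; co < Cout; ++co)
    for (R_xlen_t s = 0; s < chan_out; ++s) op[co * chan_out + s] = bias[co];
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        R_xlen_t si = (R_xlen_t)i + (R_xlen_t)X * (j + (R_xlen_t)Y * k);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              int off = dx + 2 * (dy + 2 * dz);
              R_xlen_t so = (R_xlen_t)(2*i+dx) + (R_xlen_t)OX * ((2*j+dy) + (R_xlen_t)OY * (2*k+dz));
              for (int co = 0; co < Cout; ++co) {
                double acc = 0;
                for (int ci = 0; ci < cin; ++ci)
                  acc += W(co, (arma::uword)ci * 8 + off) * xp[ci * chan_in + si];
                op[co * chan_out + so] += acc;
              }
            }
      }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout);
  return out;
}

// [[Rcpp::export]]
List upconv3d_bwd_cpp(NumericVector dy, NumericVector x, IntegerVector dim,
                      int cin, const arma::mat &W) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const int OX = 2 * X, OY = 2 * Y, OZ = 2 * Z;
  const int Cout = W.n_rows;
  const R_xlen_t chan_in = (R_xlen_t)X * Y * Z, chan_out = (R_xlen_t)OX * OY * OZ;
  arma::mat dW(Cout, (arma::uword)cin * 8, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)X * Y * Z * cin);
  const double *dyp = dy.begin(), *xp = x.begin();
  double *dxp = dx.begin();
  for (int co = 0; co < Cout; ++co)
    for (R_xlen_t s = 0; s < chan_out; ++s) db[co] += dyp[co * chan_out + s];
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        R_xlen_t si = (R_xlen_t)i + (R_xlen_t)X * (j + (R_xlen_t)Y * k);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy2 = 0; dy2 < 2; ++dy2)
            for (int dx2 = 0; dx2 < 2; ++dx2) {
              int off = dx2 + 2 * (dy2 + 2 * dz);
              R_xlen_t so = (R_xlen_t)(2*i+dx2) + (R_xlen_t)OX * ((2*j+dy2) + (R_xlen_t)OY * (2*k+dz));
              for (int co = 0; co < Cout; ++co) {
                double g = dyp[co * chan_out + so];
                if (g == 0.0) continue;
                for (int ci = 0; ci < cin; ++ci) {
                  dW(co, (arma::uword)ci * 8 + off) += g * xp[ci * chan_in + si];
                  dxp[ci * chan_in + si] += g * W(co, (arma::uword)ci * 8 + off);
                }
              }
            }
      }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, cin);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
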