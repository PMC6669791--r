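// Low-level numerical kernels: 3-D convolution (im2col + GEMM), stride-2
// transpose convolution, max pooling, nearest upsampling, surface distances,
// voxel distance-to-surface fields and connected-component labelling.
//
// Array convention (matches the R side): column-major arrays with dim
// (X, Y, Z, C); linear index i + X*(j + Y*(l + Z*c)).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Convolution arithmetic runs in single precision: the GEMM operands are
// large and memory-bound, and float halves the traffic while retaining
// far more precision than stochastic training needs.
//
// Gather padded input patches into an N x (k^3*Cin) matrix (one GEMM
// operand per forward pass). Column r = a + k*(b + k*(c + k*ci)) matches
// the memory layout of a (k,k,k,Cin,Cout) weight array; for each column
// the N entries form a shifted copy of the input volume, so the inner
// loops are contiguous runs along x.
// Grow-only scratch buffers reused across calls: repeated allocation of
// 100+ MB GEMM operands costs more in page faults than the arithmetic.
static std::vector<float>& scratch(int which, size_t n) {
  static std::vector<float> bufs[3];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

static void vol2colT(const double* x, int X, int Y, int Z, int C,
                     int k, int s, int p, arma::fmat& cols) {
  const int Xo = out_extent(X, k, s, p);
  const int Yo = out_extent(Y, k, s, p);
  const int Zo = out_extent(Z, k, s, p);
  std::fill(cols.memptr(), cols.memptr() + cols.n_elem, 0.0f);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * X * Y * Z;
    for (int c = 0; c < k; ++c)
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a) {
          float* dst = cols.colptr(a + k * (b + k * (c + k * ci)));
          // output voxel (io,jo,lo) reads input (io*s-p+a, jo*s-p+b, lo*s-p+c)
          // valid io range for this offset:
          int io0 = 0, io1 = Xo - 1;
          if (s == 1) {
            io0 = std::max(0, p - a);
            io1 = std::min(Xo - 1, X - 1 + p - a);
          }
          for (int lo = 0; lo < Zo; ++lo) {
            const int zi = lo * s - p + c;
            if (zi < 0 || zi >= Z) continue;
            for (int jo = 0; jo < Yo; ++jo) {
              const int yi = jo * s - p + b;
              if (yi < 0 || yi >= Y) continue;
              float* drow = dst + (size_t)Xo * (jo + (size_t)Yo * lo);
              const double* srow = xc + (size_t)X * (yi + (size_t)Y * zi);
              if (s == 1) {
                for (int io = io0; io <= io1; ++io)
                  drow[io] = (float)srow[io - p + a];
              } else {
                for (int io = 0; io < Xo; ++io) {
                  const int xi = io * s - p + a;
                  if (xi >= 0 && xi < X) drow[io] = (float)srow[xi];
                }
              }
            }
          }
        }
  }
}

// Scatter-add an N x (k^3*Cin) matrix back into the volume (adjoint).
static void col2volT(const arma::fmat& cols, int X, int Y, int Z, int C,
                     int k, int s, int p, double* dx) {
  const int Xo = out_extent(X, k, s, p);
  const int Yo = out_extent(Y, k, s, p);
  const int Zo = out_extent(Z, k, s, p);
  std::fill(dx, dx + (size_t)X * Y * Z * C, 0.0);
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * X * Y * Z;
    for (int c = 0; c < k; ++c)
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a) {
          const float* src = cols.colptr(a + k * (b + k * (c + k * ci)));
          for (int lo = 0; lo < Zo; ++lo) {
            const int zi = lo * s - p + c;
            if (zi < 0 || zi >= Z) continue;
            for (int jo = 0; jo < Yo; ++jo) {
              const int yi = jo * s - p + b;
              if (yi < 0 || yi >= Y) continue;
              const float* srow = src + (size_t)Xo * (jo + (size_t)Yo * lo);
              double* drow = xc + (size_t)X * (yi + (size_t)Y * zi);
              for (int io = 0; io < Xo; ++io) {
                const int xi = io * s - p + a;
                if (xi >= 0 && xi < X) drow[xi] += srow[io];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector bias,
                        int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  const int Cout = bias.size();
  const int Xo = out_extent(X, k, s, p), Yo = out_extent(Y, k, s, p), Zo = out_extent(Z, k, s, p);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("convolution output would be empty");
  const arma::uword N = (arma::uword)Xo * Yo * Zo;
  const arma::uword K = (arma::uword)k * k * k * Cin;
  arma::fmat cols(scratch(0, N * K).data(), N, K, false, true);
  vol2colT(REAL(x), X, Y, Z, Cin, k, s, p, cols);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(REAL(w)), k * k * k * Cin, Cout, false, true));
  arma::fmat Yt = cols * Wf;              // N x Cout, matches output memory
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(
      arma::rowvec(const_cast<double*>(REAL(bias)), Cout, false, true));
  Yt.each_row() += bf;
  NumericVector out((R_xlen_t)Xo * Yo * Zo * Cout);
  double* op = REAL(out);
  const float* yp = Yt.memptr();
  for (size_t i = 0; i < (size_t)out.size(); ++i) op[i] = yp[i];
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  IntegerVector yd = dy.attr("dim");
  const int Cout = yd[3];
  const arma::uword N = (arma::uword)yd[0] * yd[1] * yd[2];
  const arma::uword K = (arma::uword)k * k * k * Cin;
  arma::fmat cols(scratch(0, N * K).data(), N, K, false, true);
  vol2colT(REAL(x), X, Y, Z, Cin, k, s, p, cols);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(REAL(w)), k * k * k * Cin, Cout, false, true));
  arma::fmat Dyt = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(REAL(dy)), N, Cout, false, true));
  arma::fmat dW = cols.t() * Dyt;         // (k^3*Cin) x Cout
  arma::frowvec db = arma::sum(Dyt, 0);
  arma::fmat dxcols(scratch(1, N * K).data(), N, K, false, true);
  dxcols = Dyt * Wf.t();                  // N x (k^3*Cin)
  NumericVector dx(x.size());
  col2volT(dxcols, X, Y, Z, Cin, k, s, p, REAL(dx));
  dx.attr("dim") = xd;
  NumericVector dWv(w.size());
  { double* q = REAL(dWv); const float* s0 = dW.memptr();
    for (size_t i = 0; i < (size_t)dWv.size(); ++i) q[i] = s0[i]; }
  dWv.attr("dim") = w.attr("dim");
  NumericVector dbv(Cout);
  for (int i = 0; i < Cout; ++i) dbv[i] = db[i];
  return List::create(_["dx"] = dx, _["dw"] = dWv, _["db"] = dbv);
}

// Transpose convolution with kernel (2,2,2) and stride 2: each output voxel
// receives exactly one kernel contribution, so the op reduces to one GEMM
// per kernel offset plus a scatter.
// [[Rcpp::export]]
NumericVector convt2_fw(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[4];
  const arma::uword N = (arma::uword)X * Y * Z;
  const arma::mat Xm(const_cast<double*>(REAL(x)), N, Cin, false, true);
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((size_t)Xo * Yo * Zo * Cout);
  double* o = REAL(out);
  const double* wp = REAL(w);
  for (int c = 0; c < 2; ++c) for (int b = 0; b < 2; ++b) for (int a = 0; a < 2; ++a) {
    arma::mat Wabc(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        Wabc(ci, co) = wp[a + 2 * (b + 2 * (c + 2 * (ci + (size_t)Cin * co)))];
    arma::mat Yo_m = Xm * Wabc;           // N x Cout
    for (int co = 0; co < Cout; ++co) {
      const double* yc = Yo_m.colptr(co);
      const double bco = REAL(bias)[co];
      double* oc = o + (size_t)co * Xo * Yo * Zo;
      for (int l = 0; l < Z; ++l)
        for (int j = 0; j < Y; ++j)
          for (int i = 0; i < X; ++i)
            oc[(2 * i + a) + (size_t)Xo * ((2 * j + b) + (size_t)Yo * (2 * l + c))] =
              yc[i + (size_t)X * (j + (size_t)Y * l)] + bco;
    }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return out;
}

// [[Rcpp::export]]
List convt2_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[4];
  IntegerVector yd = dy.attr("dim");
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2];
  const arma::uword N = (arma::uword)X * Y * Z;
  const arma::mat Xm(const_cast<double*>(REAL(x)), N, Cin, false, true);
  arma::mat dXm(N, Cin, arma::fill::zeros);
  NumericVector dWv(w.size());
  double* dwp = REAL(dWv);
  const double* dyp = REAL(dy);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* dc = dyp + (size_t)co * Xo * Yo * Zo;
    double sum = 0.0;
    for (size_t n = 0; n < (size_t)Xo * Yo * Zo; ++n) sum += dc[n];
    db[co] = sum;
  }
  for (int c = 0; c < 2; ++c) for (int b = 0; b < 2; ++b) for (int a = 0; a < 2; ++a) {
    arma::mat G(N, Cout);
    for (int co = 0; co < Cout; ++co) {
      const double* dc = dyp + (size_t)co * Xo * Yo * Zo;
      double* gc = G.colptr(co);
      for (int l = 0; l < Z; ++l)
        for (int j = 0; j < Y; ++j)
          for (int i = 0; i < X; ++i)
            gc[i + (size_t)X * (j + (size_t)Y * l)] =
              dc[(2 * i + a) + (size_t)Xo * ((2 * j + b) + (size_t)Yo * (2 * l + c))];
    }
    const double* wp = REAL(w);
    arma::mat Wabc(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        Wabc(ci, co) = wp[a + 2 * (b + 2 * (c + 2 * (ci + (size_t)Cin * co)))];
    dXm += G * Wabc.t();
    arma::mat dWabc = Xm.t() * G;         // Cin x Cout
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        dwp[a + 2 * (b + 2 * (c + 2 * (ci + (size_t)Cin * co)))] = dWabc(ci, co);
  }
  NumericVector dx(dXm.begin(), dXm.end());
  dx.attr("dim") = xd;
  dWv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWv, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  if (X % 2 || Y % 2 || Z % 2) stop("max pooling requires even extents");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out((size_t)Xo * Yo * Zo * C);
  IntegerVector arg(out.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * X * Y * Z;
    for (int l = 0; l < Zo; ++l)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int c = 0; c < 2; ++c) for (int b = 0; b < 2; ++b) for (int a = 0; a < 2; ++a) {
            const size_t idx = (2 * i + a) + (size_t)X * ((2 * j + b) + (size_t)Y * (2 * l + c));
            if (xc[idx] > best) { best = xc[idx]; besti = idx; }
          }
          const size_t on = (size_t)i + (size_t)Xo * (j + (size_t)Yo * l) + (size_t)ch * Xo * Yo * Zo;
          op[on] = best;
          arg[on] = (int)(besti + (size_t)ch * X * Y * Z);
        }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["y"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector argmax, IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double* dp = REAL(dx);
  const double* dyp = REAL(dy);
  for (R_xlen_t n = 0; n < dy.size(); ++n) dp[argmax[n]] += dyp[n];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector upnn2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((size_t)Xo * Yo * Zo * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * X * Y * Z;
    double* oc = op + (size_t)ch * Xo * Yo * Zo;
    for (int l = 0; l < Zo; ++l)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i)
          oc[i + (size_t)Xo * (j + (size_t)Yo * l)] =
            xc[(i / 2) + (size_t)X * ((j / 2) + (size_t)Y * (l / 2))];
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector upnn2_bw(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2], C = yd[3];
  const int X = Xo / 2, Y = Yo / 2, Z = Zo / 2;
  NumericVector dx((size_t)X * Y * Z * C);
  const double* dyp = REAL(dy);
  double* dp = REAL(dx);
  for (int ch = 0; ch < C; ++ch) {
    const double* dc = dyp + (size_t)ch * Xo * Yo * Zo;
    double* xc = dp + (size_t)ch * X * Y * Z;
    for (int l = 0; l < Zo; ++l)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i)
          xc[(i / 2) + (size_t)X * ((j / 2) + (size_t)Y * (l / 2))] +=
            dc[i + (size_t)Xo * (j + (size_t)Yo * l)];
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return dx;
}

// Per-channel mean and biased variance over the spatial dimensions.
// [[Rcpp::export]]
List channel_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t n = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector mu(C), va(C);
  const double* xp = REAL(x);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + n * ch;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    mu[ch] = s / n;
    va[ch] = s2 / n - mu[ch] * mu[ch];
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = x * scale[channel] + shift[channel]
// [[Rcpp::export]]
NumericVector channel_affine(NumericVector x, NumericVector scale,
                             NumericVector shift) {
  IntegerVector xd = x.attr("dim");
  const size_t n = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int ch = 0; ch < C; ++ch) {
    const double sc = scale[ch], sh = shift[ch];
    const double* xc = xp + n * ch;
    double* yc = yp + n * ch;
    for (size_t i = 0; i < n; ++i) yc[i] = xc[i] * sc + sh;
  }
  y.attr("dim") = xd;
  return y;
}

// Batch-norm backward (training mode, biased variance):
//   dx = gamma*inv * (dy - mean(dy) - xhat * mean(dy*xhat))
// [[Rcpp::export]]
List bn_bw(NumericVector x, NumericVector dy, NumericVector mu,
           NumericVector inv, NumericVector gamma, bool training) {
  IntegerVector xd = x.attr("dim");
  const size_t n = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* op = REAL(dx);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + n * ch;
    const double* dc = dp + n * ch;
    double* oc = op + n * ch;
    const double m = mu[ch], iv = inv[ch];
    double sdy = 0, sdyx = 0;
    for (size_t i = 0; i < n; ++i) {
      const double xh = (xc[i] - m) * iv;
      sdy += dc[i];
      sdyx += dc[i] * xh;
    }
    dgamma[ch] = sdyx;
    dbeta[ch] = sdy;
    const double gi = gamma[ch] * iv;
    if (training) {
      const double mdy = sdy / n, mdyx = sdyx / n;
      for (size_t i = 0; i < n; ++i) {
        const double xh = (xc[i] - m) * iv;
        oc[i] = gi * (dc[i] - mdy - xh * mdyx);
      }
    } else {
      for (size_t i = 0; i < n; ++i) oc[i] = gi * dc[i];
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector prelu_fw(NumericVector x, NumericVector alpha) {
  IntegerVector xd = x.attr("dim");
  const size_t n = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int ch = 0; ch < C; ++ch) {
    const double al = alpha[ch];
    const double* xc = xp + n * ch;
    double* yc = yp + n * ch;
    for (size_t i = 0; i < n; ++i)
      yc[i] = xc[i] > 0 ? xc[i] : al * xc[i];
  }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export]]
List prelu_bw(NumericVector x, NumericVector alpha, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  const size_t n = (size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector dx(x.size()), dalpha(C);
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* op = REAL(dx);
  for (int ch = 0; ch < C; ++ch) {
    const double al = alpha[ch];
    const double* xc = xp + n * ch;
    const double* dc = dp + n * ch;
    double* oc = op + n * ch;
    double da = 0;
    for (size_t i = 0; i < n; ++i) {
      if (xc[i] > 0) {
        oc[i] = dc[i];
      } else {
        oc[i] = al * dc[i];
        da += xc[i] * dc[i];
      }
    }
    dalpha[ch] = da;
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dalpha"] = dalpha);
}

// For each point in P (n x 3, mm) the distance to the nearest point in G.
// [[Rcpp::export]]
NumericVector min_point_dists(NumericMatrix P, NumericMatrix G) {
  const int n = P.nrow(), m = G.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = px - G(j, 0), dy = py - G(j, 1), dz = pz - G(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 1-D squared-distance transform (lower envelope of parabolas), with the
// abscissa scaled by the physical voxel spacing h:
//   D(p) = min_q ( (p - q)^2 h^2 + f(q) )
static void dt1d(const double* f, double* d, int n, double h2,
                 std::vector<int>& v, std::vector<double>& z) {
  int q0 = 0;
  while (q0 < n && !R_FINITE(f[q0])) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = R_PosInf; return; }
  int k = 0;
  v[0] = q0;
  z[0] = -R_PosInf;
  z[1] = R_PosInf;
  for (int q = q0 + 1; q < n; ++q) {
    if (!R_FINITE(f[q])) continue;  // an unreachable parabola never wins
    double s;
    while (true) {
      s = ((f[q] + (double)q * q * h2) - (f[v[k]] + (double)v[k] * v[k] * h2)) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]);
    d[q] = dq * dq * h2 + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel centre to the nearest
// seed voxel centre (seed = nonzero entry of `ind`), by separable
// squared-distance transforms with anisotropic spacing.
// [[Rcpp::export]]
NumericVector edt_mm(IntegerVector ind, NumericVector spacing) {
  IntegerVector dm = ind.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2];
  const size_t V = (size_t)X * Y * Z;
  NumericVector out(V);
  double* g = REAL(out);
  for (size_t i = 0; i < V; ++i) g[i] = ind[i] ? 0.0 : R_PosInf;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  double h2 = spacing[0] * spacing[0];
  for (int l = 0; l < Z; ++l)
    for (int j = 0; j < Y; ++j) {
      double* row = g + (size_t)X * (j + (size_t)Y * l);
      bool any = false;
      for (int i = 0; i < X; ++i) { f[i] = row[i]; any |= R_FINITE(row[i]); }
      if (!any) continue;
      dt1d(f.data(), d.data(), X, h2, v, z);
      for (int i = 0; i < X; ++i) row[i] = d[i];
    }
  // y pass
  h2 = spacing[1] * spacing[1];
  for (int l = 0; l < Z; ++l)
    for (int i = 0; i < X; ++i) {
      double* col0 = g + i + (size_t)X * (size_t)Y * l;
      bool any = false;
      for (int j = 0; j < Y; ++j) { f[j] = col0[(size_t)X * j]; any |= R_FINITE(f[j]); }
      if (!any) continue;
      dt1d(f.data(), d.data(), Y, h2, v, z);
      for (int j = 0; j < Y; ++j) col0[(size_t)X * j] = d[j];
    }
  // z pass
  h2 = spacing[2] * spacing[2];
  for (int j = 0; j < Y; ++j)
    for (int i = 0; i < X; ++i) {
      double* col0 = g + i + (size_t)X * j;
      bool any = false;
      for (int l = 0; l < Z; ++l) { f[l] = col0[(size_t)X * Y * l]; any |= R_FINITE(f[l]); }
      if (!any) continue;
      dt1d(f.data(), d.data(), Z, h2, v, z);
      for (int l = 0; l < Z; ++l) col0[(size_t)X * Y * l] = d[l];
    }
  for (size_t i = 0; i < V; ++i) g[i] = std::sqrt(g[i]);
  out.attr("dim") = dm;
  return out;
}

// Connected-component labelling by breadth-first search; connectivity is
// 6, 18 or 26. Labels are assigned in raster-scan order of seed voxels, so
// the component containing the lexicographically smallest voxel gets label 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  IntegerVector lab((size_t)X * Y * Z);
  lab.attr("dim") = d;
  std::vector<std::array<int, 3>> nb;
  for (int c = -1; c <= 1; ++c) for (int b = -1; b <= 1; ++b) for (int a = -1; a <= 1; ++a) {
    const int manh = std::abs(a) + std::abs(b) + std::abs(c);
    if (manh == 0) continue;
    if (connectivity == 6 && manh > 1) continue;
    if (connectivity == 18 && manh > 2) continue;
    nb.push_back({a, b, c});
  }
  int next = 0;
  std::queue<std::array<int, 3>> q;
  for (int l = 0; l < Z; ++l)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const size_t idx = i + (size_t)X * (j + (size_t)Y * l);
        if (!mask[idx] || lab[idx]) continue;
        lab[idx] = ++next;
        q.push({i, j, l});
        while (!q.empty()) {
          const auto v = q.front(); q.pop();
          for (const auto& o : nb) {
            const int ii = v[0] + o[0], jj = v[1] + o[1], ll = v[2] + o[2];
            if (ii < 0 || ii >= X || jj < 0 || jj >= Y || ll < 0 || ll >= Z) continue;
            const size_t ni = ii + (size_t)X * (jj + (size_t)Y * ll);
            if (mask[ni] && !lab[ni]) { lab[ni] = next; q.push({ii, jj, ll}); }
          }
        }
      }
  return lab;
}
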