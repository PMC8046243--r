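// Low-level NCHW tensor kernels: 2D convolution (stride 1, symmetric zero
// padding) via im2col + BLAS, 2x2/stride-2 max pooling, and 2x2/stride-2
// transposed convolution. R arrays are column-major, so element (n,c,h,w) of
// a dim=c(N,C,H,W) array sits at n + N*(c + C*(h + H*w)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t idx4(int i1, int i2, int i3, int i4,
                            int d1, int d2, int d3) {
  return (R_xlen_t)i1 + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * (i3 + (R_xlen_t)d3 * i4));
}

// Build the im2col matrix: rows = Cin*kh*kw (r = ci + Cin*(a + kh*b)),
// cols = N*H*W (m = n + N*(h + H*w)). Output spatial size equals input
// (same padding assumed: pad = (k-1)/2 for odd k; caller passes pad).
static arma::mat im2col(const double* x, int N, int C, int H, int W,
                        int kh, int kw, int pad) {
  arma::mat cols((arma::uword)(C * kh * kw), (arma::uword)N * H * W,
                 arma::fill::zeros);
  for (int b = 0; b < kw; ++b) {
    for (int a = 0; a < kh; ++a) {
      for (int ci = 0; ci < C; ++ci) {
        int r = ci + C * (a + kh * b);
        for (int w = 0; w < W; ++w) {
          int iw = w + b - pad;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h + a - pad;
            if (ih < 0 || ih >= H) continue;
            const double* src = x + idx4(0, ci, ih, iw, N, C, H);
            for (int n = 0; n < N; ++n) {
              cols((arma::uword)r,
                   (arma::uword)n + (arma::uword)N * (h + (R_xlen_t)H * w)) = src[n];
            }
          }
        }
      }
    }
  }
  return cols;
}

static arma::mat weight_mat(const double* w, int Cout, int Cin, int kh, int kw) {
  arma::mat Wm((arma::uword)Cout, (arma::uword)(Cin * kh * kw));
  for (int b = 0; b < kw; ++b)
    for (int a = 0; a < kh; ++a)
      for (int ci = 0; ci < Cin; ++ci) {
        int r = ci + Cin * (a + kh * b);
        for (int o = 0; o < Cout; ++o)
          Wm((arma::uword)o, (arma::uword)r) = w[idx4(o, ci, a, b, Cout, Cin, kh)];
      }
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], Wd = xd[3];
  int Cout = wd[0], Cin = wd[1], kh = wd[2], kw = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", C, Cin);
  arma::mat cols = im2col(x.begin(), N, C, H, Wd, kh, kw, pad);
  arma::mat Wm = weight_mat(w.begin(), Cout, Cin, kh, kw);
  arma::mat Y = Wm * cols;  // Cout x (N*H*W)
  NumericVector out((R_xlen_t)N * Cout * H * Wd);
  out.attr("dim") = IntegerVector::create(N, Cout, H, Wd);
  double* op = out.begin();
  const double* bp = bias.begin();
  for (int wq = 0; wq < Wd; ++wq)
    for (int h = 0; h < H; ++h)
      for (int o = 0; o < Cout; ++o)
        for (int n = 0; n < N; ++n)
          op[idx4(n, o, h, wq, N, Cout, H)] =
              Y((arma::uword)o, (arma::uword)n + (arma::uword)N * (h + (R_xlen_t)H * wq)) +
              bp[o];
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], Wd = xd[3];
  int Cout = wd[0], Cin = wd[1], kh = wd[2], kw = wd[3];
  // gather dY into (Cout x N*H*W)
  arma::mat dYm((arma::uword)Cout, (arma::uword)N * H * Wd);
  const double* dp = dy.begin();
  for (int wq = 0; wq < Wd; ++wq)
    for (int h = 0; h < H; ++h)
      for (int o = 0; o < Cout; ++o)
        for (int n = 0; n < N; ++n)
          dYm((arma::uword)o, (arma::uword)n + (arma::uword)N * (h + (R_xlen_t)H * wq)) =
              dp[idx4(n, o, h, wq, N, Cout, H)];
  arma::mat cols = im2col(x.begin(), N, C, H, Wd, kh, kw, pad);
  arma::mat Wm = weight_mat(w.begin(), Cout, Cin, kh, kw);
  arma::mat dWm = dYm * cols.t();              // Cout x (Cin*kh*kw)
  arma::mat dcols = Wm.t() * dYm;              // (Cin*kh*kw) x (N*H*W)
  // db
  NumericVector db(Cout);
  for (int o = 0; o < Cout; ++o) db[o] = arma::accu(dYm.row((arma::uword)o));
  // dW back to (Cout,Cin,kh,kw)
  NumericVector dw((R_xlen_t)Cout * Cin * kh * kw);
  dw.attr("dim") = IntegerVector::create(Cout, Cin, kh, kw);
  for (int b = 0; b < kw; ++b)
    for (int a = 0; a < kh; ++a)
      for (int ci = 0; ci < Cin; ++ci) {
        int r = ci + Cin * (a + kh * b);
        for (int o = 0; o < Cout; ++o)
          dw[idx4(o, ci, a, b, Cout, Cin, kh)] = dWm((arma::uword)o, (arma::uword)r);
      }
  // col2im scatter-add -> dx
  NumericVector dx((R_xlen_t)N * C * H * Wd);
  dx.attr("dim") = IntegerVector::create(N, C, H, Wd);
  double* dxp = dx.begin();
  for (int b = 0; b < kw; ++b)
    for (int a = 0; a < kh; ++a)
      for (int ci = 0; ci < C; ++ci) {
        int r = ci + C * (a + kh * b);
        for (int wq = 0; wq < Wd; ++wq) {
          int iw = wq + b - pad;
          if (iw < 0 || iw >= Wd) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h + a - pad;
            if (ih < 0 || ih >= H) continue;
            for (int n = 0; n < N; ++n)
              dxp[idx4(n, ci, ih, iw, N, C, H)] +=
                  dcols((arma::uword)r,
                        (arma::uword)n + (arma::uword)N * (h + (R_xlen_t)H * wq));
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax linear
// indices into the input array (ties: first in column-major scan order).
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)N * C * Ho * Wo);
  IntegerVector arg((R_xlen_t)N * C * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double* xp = x.begin();
  for (int wq = 0; wq < Wo; ++wq)
    for (int h = 0; h < Ho; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -INFINITY; R_xlen_t bi = 0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              R_xlen_t ii = idx4(n, c, 2 * h + a, 2 * wq + b, N, C, H);
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          R_xlen_t oo = idx4(n, c, h, wq, N, C, Ho);
          out[oo] = best;
          arg[oo] = (int)(bi + 1);
        }
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector argmax,
                                    IntegerVector in_dim) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (learned 2x upsampling).
// Weight layout: (Cin, Cout, 2, 2).
// [[Rcpp::export]]
NumericVector cpp_convT2(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cin = wd[0], Cout = wd[1];
  if (Cin != C) stop("convT2: channel mismatch");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)N * Cout * Ho * Wo);
  out.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) op[i] = 0.0;
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a)
      for (int o = 0; o < Cout; ++o)
        for (int ci = 0; ci < C; ++ci) {
          double wv = wp[idx4(ci, o, a, b, Cin, Cout, 2)];
          if (wv == 0.0) continue;
          for (int wq = 0; wq < W; ++wq)
            for (int h = 0; h < H; ++h)
              for (int n = 0; n < N; ++n)
                op[idx4(n, o, 2 * h + a, 2 * wq + b, N, Cout, Ho)] +=
                    wv * xp[idx4(n, ci, h, wq, N, C, H)];
        }
  const double* bp = bias.begin();
  for (int wq = 0; wq < Wo; ++wq)
    for (int h = 0; h < Ho; ++h)
      for (int o = 0; o < Cout; ++o)
        for (int n = 0; n < N; ++n)
          op[idx4(n, o, h, wq, N, Cout, Ho)] += bp[o];
  return out;
}

// [[Rcpp::export]]
List cpp_convT2_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cin = wd[0], Cout = wd[1];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((R_xlen_t)N * C * H * W);
  dx.attr("dim") = IntegerVector::create(N, C, H, W);
  NumericVector dw((R_xlen_t)Cin * Cout * 4);
  dw.attr("dim") = IntegerVector::create(Cin, Cout, 2, 2);
  NumericVector db(Cout);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* dp = dy.begin();
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a)
      for (int o = 0; o < Cout; ++o)
        for (int ci = 0; ci < C; ++ci) {
          double wv = wp[idx4(ci, o, a, b, Cin, Cout, 2)];
          double acc = 0.0;
          for (int wq = 0; wq < W; ++wq)
            for (int h = 0; h < H; ++h)
              for (int n = 0; n < N; ++n) {
                double g = dp[idx4(n, o, 2 * h + a, 2 * wq + b, N, Cout, Ho)];
                acc += g * xp[idx4(n, ci, h, wq, N, C, H)];
                dx[idx4(n, ci, h, wq, N, C, H)] += g * wv;
              }
          dw[idx4(ci, o, a, b, Cin, Cout, 2)] = acc;
        }
  for (int wq = 0; wq < Wo; ++wq)
    for (int h = 0; h < Ho; ++h)
      for (int o = 0; o < Cout; ++o)
        for (int n = 0; n < N; ++n)
          db[o] += dp[idx4(n, o, h, wq, N, Cout, Ho)];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
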