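// Native CPU kernels for the segmentation network.
//
// Tensor convention everywhere: dense 4D arrays [H, W, C, N] in R's
// column-major layout (H fastest).  Convolutions use 'same' zero padding and
// stride 1; the transposed convolution is the 2x2/stride-2 decoder step, so
// every output pixel receives exactly one kernel contribution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int d[4]) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4D [H,W,C,N] array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// Gather x [H,W,C,N] into the im2col matrix M of size (H*W*N) x (k*k*C).
// Row index: h + H*w + H*W*n.  Column index: a + k*b + k*k*c, matching the
// column-major layout of a [k,k,C,Cout] weight array flattened to (k*k*C, Cout).
static arma::mat im2col(const double* x, int H, int W, int C, int N, int k) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  arma::mat M((size_t)H * W * N, (size_t)k * k * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + ((size_t)n * C + c) * HW;
      for (int b = 0; b < k; ++b) {
        for (int a = 0; a < k; ++a) {
          double* Mcol = M.colptr((size_t)a + k * b + (size_t)k * k * c);
          for (int w = 0; w < W; ++w) {
            int ws = w + b - p;
            if (ws < 0 || ws >= W) continue;
            const int h0 = std::max(0, p - a), h1 = std::min(H, H + p - a);
            const double* src = xc + (size_t)ws * H;
            double* dst = Mcol + (size_t)n * HW + (size_t)w * H;
            for (int h = h0; h < h1; ++h) dst[h] = src[h + a - p];
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add of the im2col adjoint: dM (same layout as im2col) into dx.
static void col2im(const arma::mat& dM, double* dx, int H, int W, int C, int N, int k) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = dx + ((size_t)n * C + c) * HW;
      for (int b = 0; b < k; ++b) {
        for (int a = 0; a < k; ++a) {
          const double* Mcol = dM.colptr((size_t)a + k * b + (size_t)k * k * c);
          for (int w = 0; w < W; ++w) {
            int ws = w + b - p;
            if (ws < 0 || ws >= W) continue;
            const int h0 = std::max(0, p - a), h1 = std::min(H, H + p - a);
            double* dst = xc + (size_t)ws * H;
            const double* src = Mcol + (size_t)n * HW + (size_t)w * H;
            for (int h = h0; h < h1; ++h) dst[h + a - p] += src[h];
          }
        }
      }
    }
  }
}

// Copy y-layout [H,W,Co,N] <-> gemm-layout rows (h + H*w + H*W*n) x Co.
static void mat_to_tensor(const arma::mat& Y, double* y, int H, int W, int Co, int N) {
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* src = Y.colptr(co) + (size_t)n * HW;
      double* dst = y + ((size_t)n * Co + co) * HW;
      std::copy(src, src + HW, dst);
    }
}

static arma::mat tensor_to_mat(const double* y, int H, int W, int Co, int N) {
  const size_t HW = (size_t)H * W;
  arma::mat Y(HW * N, Co);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* src = y + ((size_t)n * Co + co) * HW;
      std::copy(src, src + HW, Y.colptr(co) + (size_t)n * HW);
    }
  return Y;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  dims4(x, dx); dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Co = dw[3];
  if (dw[1] != k || dw[2] != C) stop("conv2d: weight dims do not match input");
  arma::mat M = im2col(REAL(x), H, W, C, N, k);
  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)k * k * C, Co, false, true);
  arma::mat Y = M * Wm;
  for (int co = 0; co < Co; ++co) Y.col(co) += b[co];
  NumericVector y((size_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  mat_to_tensor(Y, REAL(y), H, W, Co, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int dx_[4], dw_[4];
  dims4(x, dx_); dims4(w, dw_);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Co = dw_[3];
  arma::mat dY = tensor_to_mat(REAL(dy), H, W, Co, N);
  arma::mat M = im2col(REAL(x), H, W, C, N, k);
  arma::mat dW = M.t() * dY;
  arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)k * k * C, Co, false, true);
  arma::mat dM = dY * Wm.t();
  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(REAL(dxv), REAL(dxv) + dxv.size(), 0.0);
  col2im(dM, REAL(dxv), H, W, C, N, k);
  NumericVector dwv((size_t)k * k * C * Co);
  dwv.attr("dim") = IntegerVector::create(k, k, C, Co);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, REAL(dwv));
  NumericVector dbv(Co);
  for (int co = 0; co < Co; ++co) dbv[co] = arma::accu(dY.col(co));
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 transposed convolution, stride 2: y[2h+a, 2w+b, co] += x[h,w,ci] w[a,b,ci,co].
// [[Rcpp::export(name = ".tconv2d_fw")]]
NumericVector tconv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  dims4(x, dx); dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Co = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != C) stop("tconv2d: weight dims do not match input");
  arma::mat X = tensor_to_mat(REAL(x), H, W, C, N);       // (HWN) x C
  // Wt: C x (4*Co), column a + 2b + 4co
  arma::mat Wt(C, 4 * Co);
  const double* wp = REAL(w);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int ab = 0; ab < 4; ++ab)
        Wt(ci, ab + 4 * co) = wp[ab + 4 * ((size_t)ci + (size_t)C * co)];
  arma::mat Y = X * Wt;                                   // (HWN) x (4*Co)
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * Co * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Co, N);
  double* yp = REAL(y);
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double* yc = yp + ((size_t)n * Co + co) * HW2;
      for (int ab = 0; ab < 4; ++ab) {
        const int a = ab & 1, bb = ab >> 1;
        const double* src = Y.colptr(ab + 4 * co) + (size_t)n * HW;
        for (int w2 = 0; w2 < W; ++w2) {
          double* dst = yc + (size_t)(2 * w2 + bb) * H2 + a;
          const double* s = src + (size_t)w2 * H;
          for (int h = 0; h < H; ++h) dst[2 * h] = s[h] + b[co];
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".tconv2d_bw")]]
List tconv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int dx_[4], dw_[4];
  dims4(x, dx_); dims4(w, dw_);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Co = dw_[3], H2 = 2 * H, W2 = 2 * W;
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  // gather dy into (HWN) x (4*Co)
  arma::mat dY(HW * N, 4 * Co);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* dc = dyp + ((size_t)n * Co + co) * HW2;
      for (int ab = 0; ab < 4; ++ab) {
        const int a = ab & 1, bb = ab >> 1;
        double* dst = dY.colptr(ab + 4 * co) + (size_t)n * HW;
        for (int w2 = 0; w2 < W; ++w2) {
          const double* s = dc + (size_t)(2 * w2 + bb) * H2 + a;
          double* d = dst + (size_t)w2 * H;
          for (int h = 0; h < H; ++h) d[h] = s[2 * h];
        }
      }
    }
  arma::mat X = tensor_to_mat(REAL(x), H, W, C, N);
  arma::mat Wt(C, 4 * Co);
  const double* wp = REAL(w);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int ab = 0; ab < 4; ++ab)
        Wt(ci, ab + 4 * co) = wp[ab + 4 * ((size_t)ci + (size_t)C * co)];
  arma::mat dX = dY * Wt.t();
  arma::mat dWt = X.t() * dY;
  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  mat_to_tensor(dX, REAL(dxv), H, W, C, N);
  NumericVector dwv((size_t)4 * C * Co);
  dwv.attr("dim") = IntegerVector::create(2, 2, C, Co);
  double* dwp = REAL(dwv);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int ab = 0; ab < 4; ++ab)
        dwp[ab + 4 * ((size_t)ci + (size_t)C * co)] = dWt(ci, ab + 4 * co);
  NumericVector dbv(Co);
  for (int co = 0; co < Co; ++co) {
    double s = 0;
    for (int ab = 0; ab < 4; ++ab) s += arma::accu(dY.col(ab + 4 * co));
    dbv[co] = s;
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2.  Returns pooled tensor and the linear index (1-based,
// into the input array) of each maximum for the backward scatter.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  int d[4];
  dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* ip = REAL(idx);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t best = i00;
          double v = xp[i00];
          if (xp[i00 + 1] > v) { v = xp[i00 + 1]; best = i00 + 1; }
          if (xp[i00 + H] > v) { v = xp[i00 + H]; best = i00 + H; }
          if (xp[i00 + H + 1] > v) { v = xp[i00 + H + 1]; best = i00 + H + 1; }
          yp[o] = v;
          ip[o] = (double)(best + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// 3x3 max pooling, stride 1, 'same' padding (used by the Inception pool branch).
// [[Rcpp::export(name = ".maxpool3_fw")]]
List maxpool3_fw(NumericVector x) {
  int d[4];
  dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector idx(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* ip = REAL(idx);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h, ++o) {
          double v = -std::numeric_limits<double>::infinity();
          size_t best = 0;
          for (int bb = std::max(0, w - 1); bb <= std::min(W - 1, w + 1); ++bb)
            for (int aa = std::max(0, h - 1); aa <= std::min(H - 1, h + 1); ++aa) {
              size_t i = base + (size_t)bb * H + aa;
              if (xp[i] > v) { v = xp[i]; best = i; }
            }
          yp[o] = v;
          ip[o] = (double)(best + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}
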