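// Numerical kernels for the network engine.
//
// Feature maps are R arrays of dim (H, W, C, N), column-major, so element
// (h, w, c, n) sits at h + H*(w + W*(c + C*n)) (0-based).  Convolution
// weights are (k, k, Cin, Cout).  All convolutions are stride-1 with
// "same" zero padding p = dilation*(k-1)/2 and odd k, so spatial dims are
// preserved; downsampling is done exclusively by the pooling kernels.
// Arithmetic runs in float32 (sgemm) which is the precision segmentation
// networks train in; results are returned as doubles.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector alloc4(int H, int W, int C, int N) {
  NumericVector y((R_xlen_t)H * W * (R_xlen_t)C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; i++) d[i] = dm[i];
}

// Gather one sample's im2col matrix: rows index (h + H*w), columns index
// (kh + k*kw + k*k*ci), matching the column-major reshape of the weights.
static void im2col(const double* xn, int H, int W, int C, int k, int dil,
                   arma::fmat& cols) {
  const int off = (k - 1) / 2;
  const int HW = H * W;
  for (int ci = 0; ci < C; ci++) {
    const double* xc = xn + (size_t)ci * HW;
    for (int kw = 0; kw < k; kw++) {
      const int dw = dil * (kw - off);
      for (int kh = 0; kh < k; kh++) {
        const int dh = dil * (kh - off);
        float* col = cols.colptr(kh + k * (kw + k * ci));
        for (int w = 0; w < W; w++) {
          const int wi = w + dw;
          float* dst = col + (size_t)w * H;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + H, 0.0f);
            continue;
          }
          const double* src = xc + (size_t)wi * H;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          if (h0 > H) h0 = H;
          if (h1 < h0) h1 = h0;
          for (int h = 0; h < h0; h++) dst[h] = 0.0f;
          for (int h = h0; h < h1; h++) dst[h] = (float)src[h + dh];
          for (int h = h1; h < H; h++) dst[h] = 0.0f;
        }
      }
    }
  }
}

// Scatter-add of an im2col-layout gradient back onto the input plane.
static void col2im_add(const arma::fmat& dcols, int H, int W, int C, int k,
                       int dil, double* dxn) {
  const int off = (k - 1) / 2;
  const int HW = H * W;
  for (int ci = 0; ci < C; ci++) {
    double* dxc = dxn + (size_t)ci * HW;
    for (int kw = 0; kw < k; kw++) {
      const int dw = dil * (kw - off);
      for (int kh = 0; kh < k; kh++) {
        const int dh = dil * (kh - off);
        const float* col = dcols.colptr(kh + k * (kw + k * ci));
        for (int w = 0; w < W; w++) {
          const int wi = w + dw;
          if (wi < 0 || wi >= W) continue;
          const float* src = col + (size_t)w * H;
          double* dst = dxc + (size_t)wi * H;
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; h++) dst[h + dh] += (double)src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w,
                          Nullable<NumericVector> bias, int dilation) {
  int xd[4], wd[4];
  get_dim4(x, xd);
  get_dim4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || k % 2 == 0) stop("kernel must be square with odd size");
  if (wd[2] != C) stop("weight input channels do not match input");
  const int HW = H * W, kkC = k * k * C;

  arma::fmat Wm(kkC, Cout);
  for (int i = 0; i < kkC * Cout; i++) Wm[i] = (float)w[i];
  arma::frowvec bv(Cout, arma::fill::zeros);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int i = 0; i < Cout; i++) bv[i] = (float)b[i];
  }

  NumericVector y = alloc4(H, W, Cout, N);
  arma::fmat cols(HW, kkC);
  for (int n = 0; n < N; n++) {
    im2col(&x[0] + (size_t)n * HW * C, H, W, C, k, dilation, cols);
    arma::fmat yn = cols * Wm;
    yn.each_row() += bv;
    double* yp = &y[0] + (size_t)n * HW * Cout;
    for (int i = 0; i < HW * Cout; i++) yp[i] = (double)yn[i];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int dilation, bool need_dx, bool need_db) {
  int xd[4], wd[4];
  get_dim4(x, xd);
  get_dim4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int HW = H * W, kkC = k * k * C;

  arma::fmat Wm(kkC, Cout);
  for (int i = 0; i < kkC * Cout; i++) Wm[i] = (float)w[i];

  arma::fmat dW(kkC, Cout, arma::fill::zeros);
  arma::frowvec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) dx = alloc4(H, W, C, N);

  arma::fmat cols(HW, kkC), dyn(HW, Cout);
  for (int n = 0; n < N; n++) {
    const double* dyp = &dy[0] + (size_t)n * HW * Cout;
    for (int i = 0; i < HW * Cout; i++) dyn[i] = (float)dyp[i];
    im2col(&x[0] + (size_t)n * HW * C, H, W, C, k, dilation, cols);
    dW += cols.t() * dyn;
    if (need_db) db += arma::sum(dyn, 0);
    if (need_dx) {
      arma::fmat dcols = dyn * Wm.t();
      col2im_add(dcols, H, W, C, k, dilation, &dx[0] + (size_t)n * HW * C);
    }
  }

  NumericVector dwv = alloc4(k, k, C, Cout);
  for (int i = 0; i < kkC * Cout; i++) dwv[i] = (double)dW[i];
  List out = List::create(Named("dw") = dwv);
  if (need_db) {
    NumericVector dbv(Cout);
    for (int i = 0; i < Cout; i++) dbv[i] = (double)db[i];
    out["db"] = dbv;
  }
  if (need_dx) out["dx"] = dx;
  return out;
}

// 2x2 max pooling, stride 2.  Returns the pooled map plus the flat index of
// each selected element (R 1-based) so the backward pass is an exact scatter.
// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x) {
  int d[4];
  get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dims");
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y = alloc4(H2, W2, C, N);
  IntegerVector idx(y.size());
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    const double* plane = &x[0] + (size_t)cn * H * W;
    for (int w = 0; w < W2; w++) {
      for (int h = 0; h < H2; h++) {
        size_t base = (size_t)(2 * w) * H + 2 * h;
        size_t cand[4] = {base, base + 1, base + (size_t)H, base + (size_t)H + 1};
        size_t best = cand[0];
        for (int t = 1; t < 4; t++)
          if (plane[cand[t]] > plane[best]) best = cand[t];
        y[o] = plane[best];
        idx[o] = (int)((size_t)cn * H * W + best) + 1;
        o++;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(IntegerVector idx, NumericVector dy,
                             IntegerVector xdim) {
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < dy.size(); i++) dx[idx[i] - 1] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_avgpool2_fwd(NumericVector x) {
  int d[4];
  get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("average pooling requires even spatial dims");
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y = alloc4(H2, W2, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    const double* plane = &x[0] + (size_t)cn * H * W;
    for (int w = 0; w < W2; w++)
      for (int h = 0; h < H2; h++) {
        const double* p = plane + (size_t)(2 * w) * H + 2 * h;
        y[o++] = 0.25 * (p[0] + p[1] + p[H] + p[H + 1]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_avgpool2_bwd(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector dx = alloc4(H, W, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    double* plane = &dx[0] + (size_t)cn * H * W;
    for (int w = 0; w < W2; w++)
      for (int h = 0; h < H2; h++) {
        double g = 0.25 * dy[o++];
        double* p = plane + (size_t)(2 * w) * H + 2 * h;
        p[0] += g; p[1] += g; p[H] += g; p[H + 1] += g;
      }
  }
  return dx;
}

// Bilinear x2 upsampling, align_corners = FALSE: output pixel i samples the
// input at (i + 0.5)/2 - 0.5 with edge clamping.
struct LinTap { int i0, i1; double w0, w1; };

static std::vector<LinTap> up2_taps(int n_in) {
  std::vector<LinTap> taps(2 * n_in);
  for (int i = 0; i < 2 * n_in; i++) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int i0 = (int)std::floor(s);
    double t = s - i0;
    int i1 = i0 + 1;
    if (i0 < 0) i0 = 0;
    if (i1 > n_in - 1) i1 = n_in - 1;
    taps[i] = {i0, i1, 1.0 - t, t};
  }
  return taps;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_fwd(NumericVector x) {
  int d[4];
  get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(2 * H, 2 * W, C, N);
  std::vector<LinTap> th = up2_taps(H), tw = up2_taps(W);
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    const double* plane = &x[0] + (size_t)cn * H * W;
    for (int w = 0; w < 2 * W; w++) {
      const double* c0 = plane + (size_t)tw[w].i0 * H;
      const double* c1 = plane + (size_t)tw[w].i1 * H;
      for (int h = 0; h < 2 * H; h++) {
        const LinTap& a = th[h];
        y[o++] = tw[w].w0 * (a.w0 * c0[a.i0] + a.w1 * c0[a.i1]) +
                 tw[w].w1 * (a.w0 * c1[a.i0] + a.w1 * c1[a.i1]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bwd(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx = alloc4(H, W, C, N);
  std::vector<LinTap> th = up2_taps(H), tw = up2_taps(W);
  size_t o = 0;
  for (int cn = 0; cn < C * N; cn++) {
    double* plane = &dx[0] + (size_t)cn * H * W;
    for (int w = 0; w < 2 * W; w++) {
      double* c0 = plane + (size_t)tw[w].i0 * H;
      double* c1 = plane + (size_t)tw[w].i1 * H;
      for (int h = 0; h < 2 * H; h++) {
        const LinTap& a = th[h];
        double g = dy[o++];
        c0[a.i0] += g * tw[w].w0 * a.w0;
        c0[a.i1] += g * tw[w].w0 * a.w1;
        c1[a.i0] += g * tw[w].w1 * a.w0;
        c1[a.i1] += g * tw[w].w1 * a.w1;
      }
    }
  }
  return dx;
}

// 8-connected component labelling of a binary matrix (the connectivity the
// MATLAB bwareaopen default uses).  Stack-based flood fill; labels 1..L.
// [[Rcpp::export]]
IntegerMatrix nn_label8(NumericMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int w = 0; w < W; w++) {
    for (int h = 0; h < H; h++) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      next++;
      stack.push_back({h, w});
      lab(h, w) = next;
      while (!stack.empty()) {
        auto [ch, cw] = stack.back();
        stack.pop_back();
        for (int dw = -1; dw <= 1; dw++) {
          for (int dh = -1; dh <= 1; dh++) {
            int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back({nh, nw});
            }
          }
        }
      }
    }
  }
  return lab;
}

// --- batch norm and ReLU fast paths ---------------------------------------
// Per-channel statistics over the spatial and batch axes.
// [[Rcpp::export]]
List nn_bn_stats(NumericVector x) {
  int d[4];
  get_dim4(x, d);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; c++) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; n++) {
      const double* p = &x[0] + (size_t)(n * C + c) * HW;
      for (int i = 0; i < HW; i++) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / ((double)HW * N);
    mean[c] = m;
    double v = s2 / ((double)HW * N) - m * m;
    var[c] = v < 0 ? 0 : v;
  }
  return List::create(Named("mean") = mean, Named("var") = var);
}

// y = gamma * (x - mean) * invstd + beta, per channel.
// [[Rcpp::export]]
NumericVector nn_bn_apply(NumericVector x, NumericVector mean,
                          NumericVector invstd, NumericVector gamma,
                          NumericVector beta) {
  int d[4];
  get_dim4(x, d);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(d[0], d[1], d[2], d[3]);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double a = gamma[c] * invstd[c];
      const double b = beta[c] - a * mean[c];
      const double* p = &x[0] + (size_t)(n * C + c) * HW;
      double* q = &y[0] + (size_t)(n * C + c) * HW;
      for (int i = 0; i < HW; i++) q[i] = a * p[i] + b;
    }
  }
  return y;
}

// Training-mode batch-norm backward (batch statistics).
// [[Rcpp::export]]
List nn_bn_bwd(NumericVector x, NumericVector g, NumericVector mean,
               NumericVector invstd, NumericVector gamma) {
  int d[4];
  get_dim4(x, d);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  const double M = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx = alloc4(d[0], d[1], d[2], d[3]);
  for (int c = 0; c < C; c++) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; n++) {
      const double* px = &x[0] + (size_t)(n * C + c) * HW;
      const double* pg = &g[0] + (size_t)(n * C + c) * HW;
      for (int i = 0; i < HW; i++) {
        sg += pg[i];
        sgx += pg[i] * (px[i] - mean[c]) * invstd[c];
      }
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    const double a = gamma[c] * invstd[c];
    const double mg = sg / M, mgx = sgx / M;
    for (int n = 0; n < N; n++) {
      const double* px = &x[0] + (size_t)(n * C + c) * HW;
      const double* pg = &g[0] + (size_t)(n * C + c) * HW;
      double* pd = &dx[0] + (size_t)(n * C + c) * HW;
      for (int i = 0; i < HW; i++) {
        const double xh = (px[i] - mean[c]) * invstd[c];
        pd[i] = a * (pg[i] - mg - xh * mgx);
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// Per-channel scaling (inference-mode batch-norm backward).
// [[Rcpp::export]]
NumericVector nn_chan_scale_vec(NumericVector x, NumericVector s) {
  int d[4];
  get_dim4(x, d);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(d[0], d[1], d[2], d[3]);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      const double* p = &x[0] + (size_t)(n * C + c) * HW;
      double* q = &y[0] + (size_t)(n * C + c) * HW;
      for (int i = 0; i < HW; i++) q[i] = s[c] * p[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); i++) if (y[i] < 0) y[i] = 0;
  return y;
}

// Gradient through ReLU, masked by the forward output.
// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector y, NumericVector g) {
  NumericVector dx = clone(g);
  for (R_xlen_t i = 0; i < dx.size(); i++) if (y[i] <= 0) dx[i] = 0;
  return dx;
}
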