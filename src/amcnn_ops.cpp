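// Low-level layer primitives for the attention-masked CNN.
//
// Feature arrays cross the R boundary as dense double arrays in the R
// (column-major) layout (H, W, C, N); convolution kernels as (kh, kw, C, F).
// Internally everything runs in single precision: the convolutions are
// im2col + sgemm, which is where essentially all training time goes.

#include <RcppArmadillo.h>
using namespace Rcpp;

static void copy_to_float(const NumericVector& src, std::vector<float>& dst) {
  dst.resize(src.size());
  const double* p = src.begin();
  for (R_xlen_t i = 0; i < src.size(); ++i) dst[i] = static_cast<float>(p[i]);
}

static IntegerVector dims_of(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return d;
}

static int out_side(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Patch matrix in transposed layout: colT is (Ho*Wo) x (kh*kw*C) with
// column index r = ki + kh*(kj + kw*c), matching the column-major
// flattening of a (kh, kw, C) kernel slab.  Output position p = io + Ho*jo
// runs down each column, so for stride 1 whole runs are contiguous in both
// source and destination.
static void im2col_t(const float* x, int H, int W, int C,
                     int kh, int kw, int stride, int pad,
                     int Ho, int Wo, float* base, size_t ld, size_t row0) {
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        float* cp = base + ld * (size_t)(ki + kh * (kj + kw * c)) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          float* dst = cp + (size_t)Ho * jo;
          if (j < 0 || j >= W) {
            std::memset(dst, 0, sizeof(float) * Ho);
            continue;
          }
          const float* xj = xc + (size_t)H * j;
          if (stride == 1) {
            const int i_first = ki - pad;                // i at io = 0
            int lo = std::max(0, -i_first);              // first valid io
            int hi = std::min(Ho - 1, H - 1 - i_first);  // last valid io
            if (lo > 0) std::memset(dst, 0, sizeof(float) * lo);
            if (hi >= lo)
              std::memcpy(dst + lo, xj + i_first + lo,
                          sizeof(float) * (hi - lo + 1));
            if (hi < Ho - 1)
              std::memset(dst + hi + 1, 0, sizeof(float) * (Ho - 1 - hi));
          } else {
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride - pad + ki;
              dst[io] = (i >= 0 && i < H) ? xj[i] : 0.0f;
            }
          }
        }
      }
    }
  }
}

static void col2im_t_add(const float* base, size_t ld, size_t row0,
                         float* dx, int H, int W, int C,
                         int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    float* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const float* cp = base + ld * (size_t)(ki + kh * (kj + kw * c)) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          const float* src = cp + (size_t)Ho * jo;
          float* xj = xc + (size_t)H * j;
          if (stride == 1) {
            const int i_first = ki - pad;
            const int lo = std::max(0, -i_first);
            const int hi = std::min(Ho - 1, H - 1 - i_first);
            for (int io = lo; io <= hi; ++io) xj[i_first + io] += src[io];
          } else {
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride - pad + ki;
              if (i >= 0 && i < H) xj[i] += src[io];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("conv2d: kernel expects %d channels, input has %d", wd[2], C);
  const int Ho = out_side(H, kh, stride, pad), Wo = out_side(W, kw, stride, pad);
  const int R = kh * kw * C, P = Ho * Wo;

  std::vector<float> xf, wf;
  copy_to_float(x, xf);
  copy_to_float(w, wf);
  arma::fmat wmat(wf.data(), R, F, false, true);
  arma::frowvec bf(F, arma::fill::zeros);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int f = 0; f < F; ++f) bf[f] = (float)b[f];
  }

  NumericVector out((R_xlen_t)P * F * N);
  arma::fmat col(P, R), ymat;
  for (int n = 0; n < N; ++n) {
    im2col_t(xf.data() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
             Ho, Wo, col.memptr(), P, 0);
    ymat = col * wmat;                // P x F
    if (bias.isNotNull()) ymat.each_row() += bf;
    double* op = out.begin() + (R_xlen_t)P * F * n;
    const float* yp = ymat.memptr();
    for (R_xlen_t i = 0; i < (R_xlen_t)P * F; ++i) op[i] = yp[i];
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_dx, bool need_db) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int R = kh * kw * C, P = Ho * Wo;

  std::vector<float> xf, wf, dyf;
  copy_to_float(x, xf);
  copy_to_float(w, wf);
  copy_to_float(dy, dyf);
  arma::fmat wmat(wf.data(), R, F, false, true);

  arma::fmat dwm(R, F, arma::fill::zeros);
  arma::frowvec dbv(F, arma::fill::zeros);
  std::vector<float> dxf;
  if (need_dx) dxf.assign(xf.size(), 0.0f);

  arma::fmat col(P, R), dcol;
  for (int n = 0; n < N; ++n) {
    im2col_t(xf.data() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
             Ho, Wo, col.memptr(), P, 0);
    arma::fmat dyn(dyf.data() + (size_t)P * F * n, P, F, false, true);
    dwm += col.t() * dyn;
    if (need_db) dbv += arma::sum(dyn, 0);
    if (need_dx) {
      dcol = dyn * wmat.t();          // P x R
      col2im_t_add(dcol.memptr(), P, 0, dxf.data() + (size_t)H * W * C * n,
                   H, W, C, kh, kw, stride, pad, Ho, Wo);
    }
  }

  NumericVector dw(w.size());
  const float* dwp = dwm.memptr();
  for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = dwp[i];
  dw.attr("dim") = wd;

  List out = List::create(_["dw"] = dw);
  if (need_db) {
    NumericVector db(F);
    for (int f = 0; f < F; ++f) db[f] = dbv[f];
    out["db"] = db;
  }
  if (need_dx) {
    NumericVector dx(x.size());
    for (R_xlen_t i = 0; i < dx.size(); ++i) dx[i] = dxf[i];
    dx.attr("dim") = xd;
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_side(H, k, stride, pad), Wo = out_side(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());           // 0-based flat index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          const int i0 = io * stride - pad, j0 = jo * stride - pad;
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              const double v = xc[i + (size_t)H * j];
              if (v > best) { best = v; bi = i + H * j; }
            }
          }
          const R_xlen_t o = (R_xlen_t)(io + Ho * jo) +
                             (R_xlen_t)Ho * Wo * (c + (R_xlen_t)C * n);
          yp[o] = best;
          ip[o] = (int)(base + bi);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  double* xp = dx.begin();
  for (R_xlen_t t = 0; t < dy.size(); ++t) xp[ip[t]] += dp[t];
  dx.attr("dim") = xdim;
  return dx;
}

// Per-channel batch mean and (biased) variance over (H, W, N).
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (HW * N);
    mean[c] = m;
    var[c] = s2 / (HW * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector gamma, NumericVector beta,
                           NumericVector mean, NumericVector var, double eps) {
  IntegerVector xd = dims_of(x);
  const int C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double istd = 1.0 / std::sqrt(var[c] + eps);
      const double a = gamma[c] * istd;
      const double b = beta[c] - a * mean[c];
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) yp[off + i] = a * xp[off + i] + b;
    }
  }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma,
                NumericVector mean, NumericVector var, double eps,
                NumericVector dy) {
  IntegerVector xd = dims_of(x);
  const int C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C), dx(x.size());
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double sd = 0.0, sdx = 0.0;               // sum dy, sum dy * xhat
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double xh = (xp[off + i] - mean[c]) * istd;
        sd += dp[off + i];
        sdx += dp[off + i] * xh;
      }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double a = gamma[c] * istd / m;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double xh = (xp[off + i] - mean[c]) * istd;
        op[off + i] = a * (m * dp[off + i] - sd - xh * sdx);
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0.0 ? xp[i] : 0.0;
  if (x.hasAttribute("dim")) y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  const double* yp = y.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) op[i] = yp[i] > 0.0 ? dp[i] : 0.0;
  if (dy.hasAttribute("dim")) dx.attr("dim") = dy.attr("dim");
  return dx;
}

// y(i,j,c,n) = x(i,j,c,n) * a(i,j,n): broadcast a spatial weight map over
// channels.  Its own adjoint (gradient wrt x is the same reweighting of dy).
// [[Rcpp::export]]
NumericVector cpp_scale_spatial(NumericVector x, NumericVector a) {
  IntegerVector xd = dims_of(x);
  const int C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)xd[0] * xd[1];
  NumericVector y(x.size());
  const double* xp = x.begin();
  const double* ap = a.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* an = ap + HW * n;
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * an[i];
    }
  }
  y.attr("dim") = xd;
  return y;
}

// ---------------------------------------------------------------------------
// Fused stem and residual-block passes.  Intra-block activations stay in
// single precision inside a cache object owned by an external pointer, so
// only the (much smaller) between-stage tensors cross the R boundary.

struct TensorDims { int H, W, C, N; size_t size() const { return (size_t)H * W * C * N; } };

static void to_float_vec(const NumericVector& src, std::vector<float>& dst) {
  copy_to_float(src, dst);
}

static arma::fmat weight_mat(const NumericVector& w) {
  IntegerVector wd = w.attr("dim");
  const int R = wd[0] * wd[1] * wd[2], F = wd[3];
  arma::fmat out(R, F);
  const double* p = w.begin();
  float* q = out.memptr();
  for (size_t i = 0; i < (size_t)R * F; ++i) q[i] = (float)p[i];
  return out;
}

// Persistent scratch for the batched patch matrix and its companions, so
// the training loop does not reallocate hundreds of MB every step.
static std::vector<float>& conv_scratch_col() { static std::vector<float> s; return s; }
static std::vector<float>& conv_scratch_y() { static std::vector<float> s; return s; }

// The patch matrix is built for the whole minibatch: (N*P) x R with sample
// n occupying rows [n*P, (n+1)*P).  Each convolution is then a single
// well-shaped sgemm instead of N skinny ones.
static void conv_fwd_f(const float* x, TensorDims d, const arma::fmat& wmat,
                       int kh, int kw, int stride, int pad,
                       float* y, TensorDims& od) {
  const int Ho = out_side(d.H, kh, stride, pad), Wo = out_side(d.W, kw, stride, pad);
  const int F = wmat.n_cols, P = Ho * Wo, R = wmat.n_rows;
  const size_t NP = (size_t)P * d.N;
  od = {Ho, Wo, F, d.N};
  std::vector<float>& cbuf = conv_scratch_col();
  if (cbuf.size() < NP * R) cbuf.resize(NP * R);
  for (int n = 0; n < d.N; ++n)
    im2col_t(x + (size_t)d.H * d.W * d.C * n, d.H, d.W, d.C,
             kh, kw, stride, pad, Ho, Wo, cbuf.data(), NP, (size_t)P * n);
  arma::fmat colAll(cbuf.data(), NP, R, false, true);
  std::vector<float>& ybuf = conv_scratch_y();
  if (ybuf.size() < NP * F) ybuf.resize(NP * F);
  arma::fmat yAll(ybuf.data(), NP, F, false, true);
  yAll = colAll * wmat;
  for (int n = 0; n < d.N; ++n)
    for (int f = 0; f < F; ++f)
      std::memcpy(y + (size_t)P * F * n + (size_t)P * f,
                  ybuf.data() + NP * f + (size_t)P * n, sizeof(float) * P);
}

// accumulates dw; optionally adds dx contribution into dx (pre-zeroed)
static void conv_bwd_f(const float* x, TensorDims d, const arma::fmat& wmat,
                       int kh, int kw, int stride, int pad,
                       const float* dy, TensorDims od,
                       arma::fmat& dwm, float* dx) {
  const int P = od.H * od.W, F = od.C, R = wmat.n_rows;
  const size_t NP = (size_t)P * d.N;
  std::vector<float>& cbuf = conv_scratch_col();
  if (cbuf.size() < NP * R) cbuf.resize(NP * R);
  for (int n = 0; n < d.N; ++n)
    im2col_t(x + (size_t)d.H * d.W * d.C * n, d.H, d.W, d.C,
             kh, kw, stride, pad, od.H, od.W, cbuf.data(), NP, (size_t)P * n);
  arma::fmat colAll(cbuf.data(), NP, R, false, true);
  std::vector<float>& ybuf = conv_scratch_y();
  if (ybuf.size() < NP * F) ybuf.resize(NP * F);
  for (int n = 0; n < d.N; ++n)
    for (int f = 0; f < F; ++f)
      std::memcpy(ybuf.data() + NP * f + (size_t)P * n,
                  dy + (size_t)P * F * n + (size_t)P * f, sizeof(float) * P);
  arma::fmat dyAll(ybuf.data(), NP, F, false, true);
  dwm += colAll.t() * dyAll;
  if (dx) {
    // reuse the patch buffer for the gradient patches (colAll is no longer
    // needed once dw has been accumulated)
    arma::fmat dcolAll(cbuf.data(), NP, R, false, true);
    dcolAll = dyAll * wmat.t();
    for (int n = 0; n < d.N; ++n)
      col2im_t_add(cbuf.data(), NP, (size_t)P * n,
                   dx + (size_t)d.H * d.W * d.C * n,
                   d.H, d.W, d.C, kh, kw, stride, pad, od.H, od.W);
  }
}

// per-channel batch statistics with double accumulators
static void bn_stats_f(const float* x, TensorDims d, arma::vec& mean, arma::vec& var) {
  const size_t HW = (size_t)d.H * d.W;
  mean.set_size(d.C); var.set_size(d.C);
  for (int c = 0; c < d.C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < d.N; ++n) {
      const float* p = x + HW * (c + (size_t)d.C * n);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += (double)p[i] * p[i]; }
    }
    const double m = s / (HW * d.N);
    mean[c] = m;
    var[c] = s2 / (HW * d.N) - m * m;
  }
}

static void bn_apply_f(const float* x, TensorDims d,
                       const arma::vec& gamma, const arma::vec& beta,
                       const arma::vec& mean, const arma::vec& var, double eps,
                       bool relu, float* y) {
  const size_t HW = (size_t)d.H * d.W;
  for (int n = 0; n < d.N; ++n) {
    for (int c = 0; c < d.C; ++c) {
      const float a = (float)(gamma[c] / std::sqrt(var[c] + eps));
      const float b = (float)(beta[c] - a * mean[c]);
      const size_t off = HW * (c + (size_t)d.C * n);
      if (relu)
        for (size_t i = 0; i < HW; ++i) {
          const float v = a * x[off + i] + b;
          y[off + i] = v > 0.0f ? v : 0.0f;
        }
      else
        for (size_t i = 0; i < HW; ++i) y[off + i] = a * x[off + i] + b;
    }
  }
}

// Batch-norm backward; when `relu` the incoming dy is masked by the
// positivity of the batch-norm output (recomputed from x, no storage).
static void bn_bwd_f(const float* x, TensorDims d,
                     const arma::vec& gamma, const arma::vec& beta,
                     const arma::vec& mean, const arma::vec& var, double eps,
                     const float* dy, bool relu,
                     float* dx, arma::vec& dgamma, arma::vec& dbeta) {
  const size_t HW = (size_t)d.H * d.W;
  const double m = (double)HW * d.N;
  dgamma.set_size(d.C); dbeta.set_size(d.C);
  for (int c = 0; c < d.C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const float a = (float)(gamma[c] * istd);
    const float b = (float)(beta[c] - a * mean[c]);
    double sd = 0.0, sdx = 0.0;
    for (int n = 0; n < d.N; ++n) {
      const size_t off = HW * (c + (size_t)d.C * n);
      for (size_t i = 0; i < HW; ++i) {
        float g = dy[off + i];
        if (relu && a * x[off + i] + b <= 0.0f) g = 0.0f;
        const double xh = (x[off + i] - mean[c]) * istd;
        sd += g;
        sdx += g * xh;
      }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double k = gamma[c] * istd / m;
    for (int n = 0; n < d.N; ++n) {
      const size_t off = HW * (c + (size_t)d.C * n);
      for (size_t i = 0; i < HW; ++i) {
        float g = dy[off + i];
        if (relu && a * x[off + i] + b <= 0.0f) g = 0.0f;
        const double xh = (x[off + i] - mean[c]) * istd;
        dx[off + i] = (float)(k * (m * g - sd - xh * sdx));
      }
    }
  }
}

static NumericVector to_r_array(const float* p, TensorDims d) {
  NumericVector out((R_xlen_t)d.size());
  double* q = out.begin();
  for (size_t i = 0; i < d.size(); ++i) q[i] = p[i];
  out.attr("dim") = IntegerVector::create(d.H, d.W, d.C, d.N);
  return out;
}

static NumericVector vec_to_r(const arma::vec& v) {
  return NumericVector(v.begin(), v.end());
}

static arma::vec as_avec(const NumericVector& v) {
  return arma::vec(v.begin(), v.size());
}

struct StemCache {
  TensorDims xd, zd, pd;
  std::vector<float> x, z1;
  std::vector<int> idx;            // argmax flat index into the relu map
  arma::vec mean, var;
};

struct BlockCache {
  TensorDims xd, c1d, c2d, dcd;
  std::vector<float> x, c1, r1, c2, out, dc;
  arma::vec m1, v1, m2, v2, md, vd;
  bool has_down;
  int stride;
};

// [[Rcpp::export]]
List cpp_stem_fwd(NumericVector x, NumericVector w,
                  NumericVector gamma, NumericVector beta,
                  NumericVector run_mean, NumericVector run_var,
                  bool training, double eps, bool want_cache) {
  IntegerVector xd_ = x.attr("dim");
  TensorDims xd = {xd_[0], xd_[1], xd_[2], xd_[3]};
  StemCache* cc = new StemCache();
  to_float_vec(x, cc->x);
  cc->xd = xd;
  arma::fmat wmat = weight_mat(w);
  cc->z1.resize((size_t)out_side(xd.H, 7, 2, 3) * out_side(xd.W, 7, 2, 3) * wmat.n_cols * xd.N);
  conv_fwd_f(cc->x.data(), xd, wmat, 7, 7, 2, 3, cc->z1.data(), cc->zd);

  if (training) bn_stats_f(cc->z1.data(), cc->zd, cc->mean, cc->var);
  else { cc->mean = as_avec(run_mean); cc->var = as_avec(run_var); }
  std::vector<float> r1(cc->z1.size());
  bn_apply_f(cc->z1.data(), cc->zd, as_avec(gamma), as_avec(beta),
             cc->mean, cc->var, eps, true, r1.data());

  // 3x3/2 max pool, pad 1
  const int H = cc->zd.H, W = cc->zd.W, C = cc->zd.C, N = cc->zd.N;
  const int Ho = out_side(H, 3, 2, 1), Wo = out_side(W, 3, 2, 1);
  cc->pd = {Ho, Wo, C, N};
  NumericVector y((R_xlen_t)cc->pd.size());
  cc->idx.resize(cc->pd.size());
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const float* xc = r1.data() + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          const int i0 = io * 2 - 1, j0 = jo * 2 - 1;
          float best = -std::numeric_limits<float>::infinity();
          int bi = -1;
          for (int kj = 0; kj < 3; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < 3; ++ki) {
              const int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              const float v = xc[i + (size_t)H * j];
              if (v > best) { best = v; bi = i + H * j; }
            }
          }
          const size_t o = (size_t)(io + Ho * jo) + (size_t)Ho * Wo * (c + (size_t)C * n);
          yp[o] = best;
          cc->idx[o] = (int)(base + bi);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  List out = List::create(_["y"] = y,
                          _["mean"] = vec_to_r(cc->mean),
                          _["var"] = vec_to_r(cc->var));
  if (want_cache) out["cache"] = XPtr<StemCache>(cc, true);
  else delete cc;
  return out;
}

// [[Rcpp::export]]
List cpp_stem_bwd(SEXP cache, NumericVector w, NumericVector gamma,
                  NumericVector beta, double eps, NumericVector dy) {
  XPtr<StemCache> cc(cache);
  // un-pool
  std::vector<float> dr(cc->z1.size(), 0.0f);
  const double* dp = dy.begin();
  for (size_t t = 0; t < cc->pd.size(); ++t) dr[cc->idx[t]] += (float)dp[t];
  // fused relu + bn backward
  std::vector<float> dz(cc->z1.size());
  arma::vec dgamma, dbeta;
  bn_bwd_f(cc->z1.data(), cc->zd, as_avec(gamma), as_avec(beta),
           cc->mean, cc->var, eps, dr.data(), true, dz.data(), dgamma, dbeta);
  dr.clear(); dr.shrink_to_fit();
  arma::fmat wmat = weight_mat(w);
  arma::fmat dwm(wmat.n_rows, wmat.n_cols, arma::fill::zeros);
  conv_bwd_f(cc->x.data(), cc->xd, wmat, 7, 7, 2, 3, dz.data(), cc->zd,
             dwm, nullptr);
  NumericVector dw(w.size());
  const float* q = dwm.memptr();
  for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = q[i];
  dw.attr("dim") = w.attr("dim");
  return List::create(_["dw"] = dw, _["dgamma"] = vec_to_r(dgamma),
                      _["dbeta"] = vec_to_r(dbeta));
}

// params: conv1_w, bn1_gamma, bn1_beta, bn1_rm, bn1_rv, conv2_w, bn2_*,
// and optionally down_w, dbn_gamma, dbn_beta, dbn_rm, dbn_rv.
// [[Rcpp::export]]
List cpp_block_fwd(NumericVector x, List params, int stride, bool training,
                   double eps, bool want_cache) {
  IntegerVector xd_ = x.attr("dim");
  TensorDims xd = {xd_[0], xd_[1], xd_[2], xd_[3]};
  BlockCache* cc = new BlockCache();
  cc->xd = xd;
  cc->stride = stride;
  cc->has_down = params.containsElementNamed("down_w");
  to_float_vec(x, cc->x);

  arma::fmat w1 = weight_mat(params["conv1_w"]);
  cc->c1.resize((size_t)out_side(xd.H, 3, stride, 1) * out_side(xd.W, 3, stride, 1) * w1.n_cols * xd.N);
  conv_fwd_f(cc->x.data(), xd, w1, 3, 3, stride, 1, cc->c1.data(), cc->c1d);
  if (training) bn_stats_f(cc->c1.data(), cc->c1d, cc->m1, cc->v1);
  else { cc->m1 = as_avec(params["bn1_rm"]); cc->v1 = as_avec(params["bn1_rv"]); }
  cc->r1.resize(cc->c1.size());
  bn_apply_f(cc->c1.data(), cc->c1d, as_avec(params["bn1_gamma"]),
             as_avec(params["bn1_beta"]), cc->m1, cc->v1, eps, true,
             cc->r1.data());

  arma::fmat w2 = weight_mat(params["conv2_w"]);
  cc->c2.resize(cc->c1.size());
  conv_fwd_f(cc->r1.data(), cc->c1d, w2, 3, 3, 1, 1, cc->c2.data(), cc->c2d);
  if (training) bn_stats_f(cc->c2.data(), cc->c2d, cc->m2, cc->v2);
  else { cc->m2 = as_avec(params["bn2_rm"]); cc->v2 = as_avec(params["bn2_rv"]); }
  std::vector<float> b2(cc->c2.size());
  bn_apply_f(cc->c2.data(), cc->c2d, as_avec(params["bn2_gamma"]),
             as_avec(params["bn2_beta"]), cc->m2, cc->v2, eps, false,
             b2.data());

  const float* sc = nullptr;
  std::vector<float> scbuf;
  if (cc->has_down) {
    arma::fmat wd = weight_mat(params["down_w"]);
    cc->dc.resize(cc->c2.size());
    conv_fwd_f(cc->x.data(), xd, wd, 1, 1, stride, 0, cc->dc.data(), cc->dcd);
    if (training) bn_stats_f(cc->dc.data(), cc->dcd, cc->md, cc->vd);
    else { cc->md = as_avec(params["dbn_rm"]); cc->vd = as_avec(params["dbn_rv"]); }
    scbuf.resize(cc->dc.size());
    bn_apply_f(cc->dc.data(), cc->dcd, as_avec(params["dbn_gamma"]),
               as_avec(params["dbn_beta"]), cc->md, cc->vd, eps, false,
               scbuf.data());
    sc = scbuf.data();
  } else {
    sc = cc->x.data();
  }

  cc->out.resize(cc->c2.size());
  for (size_t i = 0; i < cc->out.size(); ++i) {
    const float v = b2[i] + sc[i];
    cc->out[i] = v > 0.0f ? v : 0.0f;
  }

  List out = List::create(_["y"] = to_r_array(cc->out.data(), cc->c2d));
  if (training) {
    out["bn1_mean"] = vec_to_r(cc->m1); out["bn1_var"] = vec_to_r(cc->v1);
    out["bn2_mean"] = vec_to_r(cc->m2); out["bn2_var"] = vec_to_r(cc->v2);
    if (cc->has_down) {
      out["dbn_mean"] = vec_to_r(cc->md); out["dbn_var"] = vec_to_r(cc->vd);
    }
  }
  if (want_cache) out["cache"] = XPtr<BlockCache>(cc, true);
  else delete cc;
  return out;
}

// [[Rcpp::export]]
List cpp_block_bwd(SEXP cache, List params, double eps, NumericVector dy,
                   bool need_dx) {
  XPtr<BlockCache> cc(cache);
  const size_t n_out = cc->out.size();
  std::vector<float> d(n_out);
  const double* dp = dy.begin();
  for (size_t i = 0; i < n_out; ++i)
    d[i] = cc->out[i] > 0.0f ? (float)dp[i] : 0.0f;

  arma::vec dg2, db2;
  std::vector<float> dz2(n_out);
  bn_bwd_f(cc->c2.data(), cc->c2d, as_avec(params["bn2_gamma"]),
           as_avec(params["bn2_beta"]), cc->m2, cc->v2, eps, d.data(), false,
           dz2.data(), dg2, db2);

  arma::fmat w2 = weight_mat(params["conv2_w"]);
  arma::fmat dw2(w2.n_rows, w2.n_cols, arma::fill::zeros);
  std::vector<float> dr1(cc->r1.size(), 0.0f);
  conv_bwd_f(cc->r1.data(), cc->c1d, w2, 3, 3, 1, 1, dz2.data(), cc->c2d,
             dw2, dr1.data());
  dz2.clear(); dz2.shrink_to_fit();
  for (size_t i = 0; i < dr1.size(); ++i)
    if (cc->r1[i] <= 0.0f) dr1[i] = 0.0f;

  arma::vec dg1, db1;
  std::vector<float> dz1(cc->c1.size());
  bn_bwd_f(cc->c1.data(), cc->c1d, as_avec(params["bn1_gamma"]),
           as_avec(params["bn1_beta"]), cc->m1, cc->v1, eps, dr1.data(), false,
           dz1.data(), dg1, db1);
  dr1.clear(); dr1.shrink_to_fit();

  arma::fmat w1 = weight_mat(params["conv1_w"]);
  arma::fmat dw1(w1.n_rows, w1.n_cols, arma::fill::zeros);
  std::vector<float> dx;
  if (need_dx) dx.assign(cc->x.size(), 0.0f);
  conv_bwd_f(cc->x.data(), cc->xd, w1, 3, 3, cc->stride, 1, dz1.data(),
             cc->c1d, dw1, need_dx ? dx.data() : nullptr);
  dz1.clear(); dz1.shrink_to_fit();

  List out;
  auto wgrad = [](const arma::fmat& dwm, NumericVector wref) {
    NumericVector dw(wref.size());
    const float* q = dwm.memptr();
    for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = q[i];
    dw.attr("dim") = wref.attr("dim");
    return dw;
  };
  out["conv1_dw"] = wgrad(dw1, params["conv1_w"]);
  out["bn1_dgamma"] = vec_to_r(dg1); out["bn1_dbeta"] = vec_to_r(db1);
  out["conv2_dw"] = wgrad(dw2, params["conv2_w"]);
  out["bn2_dgamma"] = vec_to_r(dg2); out["bn2_dbeta"] = vec_to_r(db2);

  if (cc->has_down) {
    arma::vec dgd, dbd;
    std::vector<float> dzd(n_out);
    bn_bwd_f(cc->dc.data(), cc->dcd, as_avec(params["dbn_gamma"]),
             as_avec(params["dbn_beta"]), cc->md, cc->vd, eps, d.data(), false,
             dzd.data(), dgd, dbd);
    arma::fmat wdm = weight_mat(params["down_w"]);
    arma::fmat dwd(wdm.n_rows, wdm.n_cols, arma::fill::zeros);
    conv_bwd_f(cc->x.data(), cc->xd, wdm, 1, 1, cc->stride, 0, dzd.data(),
               cc->dcd, dwd, need_dx ? dx.data() : nullptr);
    out["down_dw"] = wgrad(dwd, params["down_w"]);
    out["dbn_dgamma"] = vec_to_r(dgd); out["dbn_dbeta"] = vec_to_r(dbd);
  } else if (need_dx) {
    for (size_t i = 0; i < dx.size(); ++i) dx[i] += d[i];
  }
  if (need_dx) {
    NumericVector dxr((R_xlen_t)cc->x.size());
    double* q = dxr.begin();
    for (size_t i = 0; i < dx.size(); ++i) q[i] = dx[i];
    dxr.attr("dim") = IntegerVector::create(cc->xd.H, cc->xd.W, cc->xd.C, cc->xd.N);
    out["dx"] = dxr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Whole-backbone fused pass: stem -> attention -> 4 residual stages with the
// SPP branch on the Block1 output and global average pooling of Block4,
// returning the concatenated feature matrix.  Every activation stays in a
// single-precision cache that is reused across minibatches, so per-step
// R-side traffic is just the input batch and the (small) feature head.

struct ConvP { arma::fmat w; IntegerVector dims; int kh, kw, C, F, stride, pad; };
struct BNP { arma::vec gamma, beta; };

static ConvP parse_conv(List node, int stride, int pad) {
  NumericVector w = node["w"];
  IntegerVector wd = w.attr("dim");
  ConvP p;
  p.w = weight_mat(w);
  p.dims = wd;
  p.kh = wd[0]; p.kw = wd[1]; p.C = wd[2]; p.F = wd[3];
  p.stride = stride; p.pad = pad;
  return p;
}

static BNP parse_bn(List node) {
  BNP b;
  b.gamma = as_avec(node["gamma"]);
  b.beta = as_avec(node["beta"]);
  return b;
}

struct BlockState {
  std::vector<float> c1, r1, c2, out, dc;
  TensorDims xd, c1d, c2d;
  arma::vec m1, v1, m2, v2, md, vd;
  bool has_down;
};

struct BackboneCache {
  std::vector<float> x0, z1, pa, wmap;
  std::vector<int> pool_idx;
  TensorDims x0d, z1d, pad_;
  arma::vec stem_m, stem_v;
  BlockState blk[8];
  std::vector<int> spp_idx;    // flat argmax into block-2 output (max pooling)
  int spp_D;
  bool has_wmap;
};

static void run_block(BlockState& s, const float* x, TensorDims xd,
                      List bl, int stride, bool training, double eps,
                      List& rstats) {
  s.xd = xd;
  ConvP c1 = parse_conv(bl["conv1"], stride, 1);
  List bn1 = bl["bn1"], bn2 = bl["bn2"];
  BNP b1 = parse_bn(bn1), b2 = parse_bn(bn2);
  s.has_down = bl.containsElementNamed("down") && !Rf_isNull(bl["down"]);

  s.c1.resize((size_t)out_side(xd.H, 3, stride, 1) * out_side(xd.W, 3, stride, 1) * c1.F * xd.N);
  conv_fwd_f(x, xd, c1.w, 3, 3, stride, 1, s.c1.data(), s.c1d);
  if (training) bn_stats_f(s.c1.data(), s.c1d, s.m1, s.v1);
  else { s.m1 = as_avec(bn1["run_mean"]); s.v1 = as_avec(bn1["run_var"]); }
  s.r1.resize(s.c1.size());
  bn_apply_f(s.c1.data(), s.c1d, b1.gamma, b1.beta, s.m1, s.v1, eps, true, s.r1.data());

  ConvP c2 = parse_conv(bl["conv2"], 1, 1);
  s.c2.resize(s.c1.size());
  conv_fwd_f(s.r1.data(), s.c1d, c2.w, 3, 3, 1, 1, s.c2.data(), s.c2d);
  if (training) bn_stats_f(s.c2.data(), s.c2d, s.m2, s.v2);
  else { s.m2 = as_avec(bn2["run_mean"]); s.v2 = as_avec(bn2["run_var"]); }
  std::vector<float> b2o(s.c2.size());
  bn_apply_f(s.c2.data(), s.c2d, b2.gamma, b2.beta, s.m2, s.v2, eps, false, b2o.data());

  const float* sc;
  std::vector<float> scbuf;
  if (s.has_down) {
    List down = bl["down"];
    ConvP cd = parse_conv(down["conv"], stride, 0);
    List dbn = down["bn"];
    BNP bd = parse_bn(dbn);
    TensorDims dcd;
    s.dc.resize(s.c2.size());
    conv_fwd_f(x, xd, cd.w, 1, 1, stride, 0, s.dc.data(), dcd);
    if (training) bn_stats_f(s.dc.data(), s.c2d, s.md, s.vd);
    else { s.md = as_avec(dbn["run_mean"]); s.vd = as_avec(dbn["run_var"]); }
    scbuf.resize(s.dc.size());
    bn_apply_f(s.dc.data(), s.c2d, bd.gamma, bd.beta, s.md, s.vd, eps, false, scbuf.data());
    sc = scbuf.data();
  } else {
    sc = x;
  }
  s.out.resize(s.c2.size());
  for (size_t i = 0; i < s.out.size(); ++i) {
    const float v = b2o[i] + sc[i];
    s.out[i] = v > 0.0f ? v : 0.0f;
  }
  if (training) {
    rstats["bn1_mean"] = vec_to_r(s.m1); rstats["bn1_var"] = vec_to_r(s.v1);
    rstats["bn2_mean"] = vec_to_r(s.m2); rstats["bn2_var"] = vec_to_r(s.v2);
    if (s.has_down) {
      rstats["dbn_mean"] = vec_to_r(s.md); rstats["dbn_var"] = vec_to_r(s.vd);
    }
  }
}

// Backward through one block; dy is consumed, dx written into `dx` (sized,
// zeroed by caller).  Returns the nested gradient list for the block.
static List run_block_bwd(BlockState& s, const float* x, List bl,
                          int stride, double eps, std::vector<float>& dy,
                          float* dx) {
  const size_t n_out = s.out.size();
  for (size_t i = 0; i < n_out; ++i)
    if (s.out[i] <= 0.0f) dy[i] = 0.0f;

  List bn1 = bl["bn1"], bn2 = bl["bn2"];
  BNP b1 = parse_bn(bn1), b2 = parse_bn(bn2);
  arma::vec dg2, db2;
  std::vector<float> dz2(n_out);
  bn_bwd_f(s.c2.data(), s.c2d, b2.gamma, b2.beta, s.m2, s.v2, eps,
           dy.data(), false, dz2.data(), dg2, db2);

  ConvP c2 = parse_conv(bl["conv2"], 1, 1);
  arma::fmat dw2(c2.w.n_rows, c2.w.n_cols, arma::fill::zeros);
  std::vector<float> dr1(s.r1.size(), 0.0f);
  conv_bwd_f(s.r1.data(), s.c1d, c2.w, 3, 3, 1, 1, dz2.data(), s.c2d,
             dw2, dr1.data());
  dz2.clear(); dz2.shrink_to_fit();
  for (size_t i = 0; i < dr1.size(); ++i)
    if (s.r1[i] <= 0.0f) dr1[i] = 0.0f;

  arma::vec dg1, db1;
  std::vector<float> dz1(s.c1.size());
  bn_bwd_f(s.c1.data(), s.c1d, b1.gamma, b1.beta, s.m1, s.v1, eps,
           dr1.data(), false, dz1.data(), dg1, db1);
  dr1.clear(); dr1.shrink_to_fit();

  ConvP c1 = parse_conv(bl["conv1"], stride, 1);
  arma::fmat dw1(c1.w.n_rows, c1.w.n_cols, arma::fill::zeros);
  conv_bwd_f(x, s.xd, c1.w, 3, 3, stride, 1, dz1.data(), s.c1d, dw1, dx);
  dz1.clear(); dz1.shrink_to_fit();

  auto wgrad = [](const arma::fmat& dwm, const IntegerVector& dims) {
    NumericVector dw((R_xlen_t)dwm.n_elem);
    const float* q = dwm.memptr();
    for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = q[i];
    dw.attr("dim") = dims;
    return dw;
  };
  List g = List::create(
    _["conv1"] = List::create(_["w"] = wgrad(dw1, c1.dims)),
    _["bn1"] = List::create(_["gamma"] = vec_to_r(dg1), _["beta"] = vec_to_r(db1),
                            _["batch_mean"] = vec_to_r(s.m1),
                            _["batch_var"] = vec_to_r(s.v1)),
    _["conv2"] = List::create(_["w"] = wgrad(dw2, c2.dims)),
    _["bn2"] = List::create(_["gamma"] = vec_to_r(dg2), _["beta"] = vec_to_r(db2),
                            _["batch_mean"] = vec_to_r(s.m2),
                            _["batch_var"] = vec_to_r(s.v2)));
  if (s.has_down) {
    List down = bl["down"];
    List dbn = down["bn"];
    BNP bd = parse_bn(dbn);
    arma::vec dgd, dbd;
    std::vector<float> dzd(n_out);
    bn_bwd_f(s.dc.data(), s.c2d, bd.gamma, bd.beta, s.md, s.vd, eps,
             dy.data(), false, dzd.data(), dgd, dbd);
    ConvP cd = parse_conv(down["conv"], stride, 0);
    arma::fmat dwd(cd.w.n_rows, cd.w.n_cols, arma::fill::zeros);
    conv_bwd_f(x, s.xd, cd.w, 1, 1, stride, 0, dzd.data(), s.c2d, dwd, dx);
    g["down"] = List::create(
      _["conv"] = List::create(_["w"] = wgrad(dwd, cd.dims)),
      _["bn"] = List::create(_["gamma"] = vec_to_r(dgd), _["beta"] = vec_to_r(dbd),
                             _["batch_mean"] = vec_to_r(s.md),
                             _["batch_var"] = vec_to_r(s.vd)));
  } else {
    for (size_t i = 0; i < n_out; ++i) dx[i] += dy[i];
  }
  return g;
}

// [[Rcpp::export]]
List cpp_backbone_fwd(NumericVector x, List layers,
                      Nullable<NumericVector> weight_maps,
                      IntegerVector spp_levels, bool spp_max,
                      bool training, double eps, bool want_cache,
                      SEXP reuse) {
  IntegerVector xd_ = x.attr("dim");
  BackboneCache* cc;
  const bool fresh = Rf_isNull(reuse);
  if (!fresh) cc = (BackboneCache*)R_ExternalPtrAddr(reuse);
  else cc = new BackboneCache();
  cc->x0d = {xd_[0], xd_[1], xd_[2], xd_[3]};
  copy_to_float(x, cc->x0);

  // stem conv + BN/ReLU + 3x3/2 max pool
  List conv1 = layers["conv1"], bn1l = layers["bn1"];
  ConvP c1 = parse_conv(conv1, 2, 3);
  BNP b1 = parse_bn(bn1l);
  cc->z1.resize((size_t)out_side(cc->x0d.H, 7, 2, 3) *
                out_side(cc->x0d.W, 7, 2, 3) * c1.F * cc->x0d.N);
  conv_fwd_f(cc->x0.data(), cc->x0d, c1.w, 7, 7, 2, 3, cc->z1.data(), cc->z1d);
  if (training) bn_stats_f(cc->z1.data(), cc->z1d, cc->stem_m, cc->stem_v);
  else { cc->stem_m = as_avec(bn1l["run_mean"]); cc->stem_v = as_avec(bn1l["run_var"]); }
  std::vector<float> r1(cc->z1.size());
  bn_apply_f(cc->z1.data(), cc->z1d, b1.gamma, b1.beta, cc->stem_m, cc->stem_v,
             eps, true, r1.data());

  const int H = cc->z1d.H, W = cc->z1d.W, C = cc->z1d.C, N = cc->z1d.N;
  const int Ho = out_side(H, 3, 2, 1), Wo = out_side(W, 3, 2, 1);
  cc->pad_ = {Ho, Wo, C, N};
  cc->pa.resize(cc->pad_.size());
  cc->pool_idx.resize(cc->pad_.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const float* xc = r1.data() + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          const int i0 = io * 2 - 1, j0 = jo * 2 - 1;
          float best = -std::numeric_limits<float>::infinity();
          int bi = -1;
          for (int kj = 0; kj < 3; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < 3; ++ki) {
              const int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              const float v = xc[i + (size_t)H * j];
              if (v > best) { best = v; bi = i + H * j; }
            }
          }
          const size_t o = (size_t)(io + Ho * jo) + (size_t)Ho * Wo * (c + (size_t)C * n);
          cc->pa[o] = best;
          cc->pool_idx[o] = (int)(base + bi);
        }
      }
    }
  }
  r1.clear(); r1.shrink_to_fit();

  // attention: multiply by the spatial weight map, broadcast over channels
  cc->has_wmap = weight_maps.isNotNull();
  if (cc->has_wmap) {
    NumericVector wm(weight_maps);
    copy_to_float(wm, cc->wmap);
    const size_t HWp = (size_t)Ho * Wo;
    for (int n = 0; n < N; ++n) {
      const float* an = cc->wmap.data() + HWp * n;
      for (int c = 0; c < C; ++c) {
        float* p = cc->pa.data() + HWp * (c + (size_t)C * n);
        for (size_t i = 0; i < HWp; ++i) p[i] *= an[i];
      }
    }
  }

  // residual stages
  const char* stage_names[4] = {"stage1", "stage2", "stage3", "stage4"};
  const int strides[4] = {1, 2, 2, 2};
  List stats;
  const float* cur = cc->pa.data();
  TensorDims curd = cc->pad_;
  int bi = 0;
  for (int st = 0; st < 4; ++st) {
    List stage = layers[stage_names[st]];
    List rs1, rs2;
    if (training) { rs1 = List::create(); rs2 = List::create(); }
    run_block(cc->blk[bi], cur, curd, stage["block1"], strides[st], training, eps, rs1);
    cur = cc->blk[bi].out.data(); curd = cc->blk[bi].c2d; ++bi;
    run_block(cc->blk[bi], cur, curd, stage["block2"], 1, training, eps, rs2);
    cur = cc->blk[bi].out.data(); curd = cc->blk[bi].c2d; ++bi;
    if (training)
      stats[stage_names[st]] = List::create(_["block1"] = rs1, _["block2"] = rs2);
  }

  // SPP on the Block1 (stage 1) output
  const BlockState& s1 = cc->blk[1];
  const int S_H = s1.c2d.H, S_W = s1.c2d.W, S_C = s1.c2d.C;
  int sumL2 = 0;
  for (int l : spp_levels) sumL2 += l * l;
  const int D_spp = S_C * sumL2;
  cc->spp_D = D_spp;
  const int C5 = curd.C;                       // Block4 channels
  const int D = D_spp + C5;
  NumericMatrix feat(D, N);
  if (spp_max) cc->spp_idx.assign((size_t)D_spp * N, 0);
  for (int n = 0; n < N; ++n) {
    int row0 = 0;
    const float* xn = s1.out.data() + (size_t)S_H * S_W * S_C * n;
    for (int l : spp_levels) {
      for (int bj = 0; bj < l; ++bj) {
        for (int bi2 = 0; bi2 < l; ++bi2) {
          const int r0 = (bi2 * S_H) / l, r1e = ((bi2 + 1) * S_H) / l;
          const int q0 = (bj * S_W) / l, q1 = ((bj + 1) * S_W) / l;
          for (int c = 0; c < S_C; ++c) {
            const float* xc = xn + (size_t)S_H * S_W * c;
            if (spp_max) {
              float best = -std::numeric_limits<float>::infinity();
              int bidx = -1;
              for (int j = q0; j < q1; ++j)
                for (int i = r0; i < r1e; ++i) {
                  const float v = xc[i + (size_t)S_H * j];
                  if (v > best) { best = v; bidx = i + S_H * j; }
                }
              feat(row0 + c, n) = best;
              cc->spp_idx[(size_t)(row0 + c) + (size_t)D_spp * n] =
                (int)((size_t)S_H * S_W * (c + (size_t)S_C * n) + bidx);
            } else {
              double acc = 0.0;
              for (int j = q0; j < q1; ++j)
                for (int i = r0; i < r1e; ++i) acc += xc[i + (size_t)S_H * j];
              feat(row0 + c, n) = acc / ((r1e - r0) * (q1 - q0));
            }
          }
          row0 += S_C;
        }
      }
    }
    // global average pool of Block4
    const float* b4 = cur + (size_t)curd.H * curd.W * curd.C * n;
    const size_t HW4 = (size_t)curd.H * curd.W;
    for (int c = 0; c < C5; ++c) {
      double acc = 0.0;
      const float* xc = b4 + HW4 * c;
      for (size_t i = 0; i < HW4; ++i) acc += xc[i];
      feat(D_spp + c, n) = acc / HW4;
    }
  }

  List out = List::create(_["feat"] = feat);
  if (training) {
    out["stats"] = stats;
    out["stem_mean"] = vec_to_r(cc->stem_m);
    out["stem_var"] = vec_to_r(cc->stem_v);
  }
  if (want_cache) {
    if (fresh) out["cache"] = XPtr<BackboneCache>(cc, true);
    else out["cache"] = reuse;
  } else if (fresh) {
    delete cc;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_backbone_bwd(SEXP cache, List layers, NumericMatrix dfeat,
                      IntegerVector spp_levels, bool spp_max, double eps) {
  XPtr<BackboneCache> cc(cache);
  const int D_spp = cc->spp_D;
  const int N = cc->x0d.N;
  const BlockState& s1 = cc->blk[1];
  const BlockState& s8 = cc->blk[7];
  const int S_H = s1.c2d.H, S_W = s1.c2d.W, S_C = s1.c2d.C;

  // gap backward into Block4-output gradient
  std::vector<float> dcur(s8.out.size(), 0.0f);
  const size_t HW4 = (size_t)s8.c2d.H * s8.c2d.W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < s8.c2d.C; ++c) {
      const float g = (float)(dfeat(D_spp + c, n) / HW4);
      float* p = dcur.data() + HW4 * (c + (size_t)s8.c2d.C * n);
      for (size_t i = 0; i < HW4; ++i) p[i] = g;
    }

  // backward through stages 4..2 (blocks 7..2)
  const char* stage_names[4] = {"stage1", "stage2", "stage3", "stage4"};
  const int strides[4] = {1, 2, 2, 2};
  List grads;
  std::vector<float> dprev;
  for (int st = 3; st >= 1; --st) {
    List stage = layers[stage_names[st]];
    BlockState& sb2 = cc->blk[2 * st + 1];
    BlockState& sb1 = cc->blk[2 * st];
    dprev.assign(sb2.xd.size(), 0.0f);
    List g2 = run_block_bwd(sb2, cc->blk[2 * st].out.data(), stage["block2"],
                            1, eps, dcur, dprev.data());
    const float* xin = (st == 1) ? cc->blk[1].out.data() : cc->blk[2 * st - 1].out.data();
    dcur.assign(sb1.xd.size(), 0.0f);
    List g1 = run_block_bwd(sb1, xin, stage["block1"], strides[st], eps,
                            dprev, dcur.data());
    grads[stage_names[st]] = List::create(_["block1"] = g1, _["block2"] = g2);
  }

  // add the SPP branch gradient into the Block1(stage1 block2) output grad
  if (spp_max) {
    for (int n = 0; n < N; ++n)
      for (int r = 0; r < D_spp; ++r)
        dcur[cc->spp_idx[(size_t)r + (size_t)D_spp * n]] += (float)dfeat(r, n);
  } else {
    for (int n = 0; n < N; ++n) {
      int row0 = 0;
      float* dn = dcur.data() + (size_t)S_H * S_W * S_C * n;
      for (int l : spp_levels) {
        for (int bj = 0; bj < l; ++bj)
          for (int bi2 = 0; bi2 < l; ++bi2) {
            const int r0 = (bi2 * S_H) / l, r1e = ((bi2 + 1) * S_H) / l;
            const int q0 = (bj * S_W) / l, q1 = ((bj + 1) * S_W) / l;
            const float inv = 1.0f / ((r1e - r0) * (q1 - q0));
            for (int c = 0; c < S_C; ++c) {
              const float g = (float)dfeat(row0 + c, n) * inv;
              float* xc = dn + (size_t)S_H * S_W * c;
              for (int j = q0; j < q1; ++j)
                for (int i = r0; i < r1e; ++i) xc[i + (size_t)S_H * j] += g;
            }
            row0 += S_C;
          }
      }
    }
  }

  // stage 1 backward
  {
    List stage = layers["stage1"];
    dprev.assign(cc->blk[1].xd.size(), 0.0f);
    List g2 = run_block_bwd(cc->blk[1], cc->blk[0].out.data(), stage["block2"],
                            1, eps, dcur, dprev.data());
    dcur.assign(cc->blk[0].xd.size(), 0.0f);
    List g1 = run_block_bwd(cc->blk[0], cc->pa.data(), stage["block1"],
                            strides[0], eps, dprev, dcur.data());
    grads["stage1"] = List::create(_["block1"] = g1, _["block2"] = g2);
  }

  // attention backward: same spatial reweighting on the gradient
  if (cc->has_wmap) {
    const size_t HWp = (size_t)cc->pad_.H * cc->pad_.W;
    for (int n = 0; n < N; ++n) {
      const float* an = cc->wmap.data() + HWp * n;
      for (int c = 0; c < cc->pad_.C; ++c) {
        float* p = dcur.data() + HWp * (c + (size_t)cc->pad_.C * n);
        for (size_t i = 0; i < HWp; ++i) p[i] *= an[i];
      }
    }
  }

  // un-pool, fused ReLU+BN backward, stem conv weight gradient
  std::vector<float> dr(cc->z1.size(), 0.0f);
  for (size_t t = 0; t < cc->pad_.size(); ++t)
    dr[cc->pool_idx[t]] += dcur[t];
  List bn1l = layers["bn1"];
  BNP b1 = parse_bn(bn1l);
  std::vector<float> dz(cc->z1.size());
  arma::vec dgamma, dbeta;
  bn_bwd_f(cc->z1.data(), cc->z1d, b1.gamma, b1.beta, cc->stem_m, cc->stem_v,
           eps, dr.data(), true, dz.data(), dgamma, dbeta);
  dr.clear(); dr.shrink_to_fit();
  List conv1 = layers["conv1"];
  ConvP c1 = parse_conv(conv1, 2, 3);
  arma::fmat dwm(c1.w.n_rows, c1.w.n_cols, arma::fill::zeros);
  conv_bwd_f(cc->x0.data(), cc->x0d, c1.w, 7, 7, 2, 3, dz.data(), cc->z1d,
             dwm, nullptr);
  NumericVector dw((R_xlen_t)dwm.n_elem);
  const float* q = dwm.memptr();
  for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = q[i];
  dw.attr("dim") = c1.dims;
  grads["conv1"] = List::create(_["w"] = dw);
  grads["bn1"] = List::create(_["gamma"] = vec_to_r(dgamma),
                              _["beta"] = vec_to_r(dbeta),
                              _["batch_mean"] = vec_to_r(cc->stem_m),
                              _["batch_var"] = vec_to_r(cc->stem_v));
  return grads;
}
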