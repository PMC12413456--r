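// Batched 2-D convolution and leaky-integrator recurrences for the
// scale-channel network. Arrays use R's column-major layout:
// inputs (H, W, C, T), weights (k, k, Cin, Cout), outputs (Ho, Wo, Cout, T).
// Convolutions are realized as per-frame im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col_frame(const double* x, int H, int W, int Cin, int k,
                         int stride, int pad, arma::mat& M) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        double* col = M.colptr(q);
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride - pad + kj;
          double* dst = col + (size_t)ow * Ho;
          if (w < 0 || w >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)w * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride - pad + ki;
            dst[oh] = (h >= 0 && h < H) ? src[h] : 0.0;
          }
        }
      }
    }
  }
}

// Event-driven sparse convolution: exploits that the input tensor (polarity
// events) is overwhelmingly zero. For every nonzero input sample the
// compatible (output position, kernel tap) pairs are enumerated directly.
// [[Rcpp::export]]
NumericVector conv2d_fwd_sparse(NumericVector x, NumericVector w, int stride,
                                int pad) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], T = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) {
    stop("conv2d_fwd_sparse: weight shape mismatch");
  }
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * Cout * T);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, T);
  const double* wp = &w[0];
  const size_t ktap = (size_t)k * k;
  for (int t = 0; t < T; ++t) {
    const double* xt = &x[0] + (size_t)t * H * W * Cin;
    double* yt = &y[0] + (size_t)t * Ho * Wo * Cout;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xt + (size_t)ci * H * W;
      for (int wcol = 0; wcol < W; ++wcol) {
        const int ow_lo = std::max(0, (wcol + pad - k + stride) / stride);
        const int ow_hi = std::min(Wo - 1, (wcol + pad) / stride);
        for (int h = 0; h < H; ++h) {
          const double v = xc[h + (size_t)wcol * H];
          if (v == 0.0) continue;
          const int oh_lo = std::max(0, (h + pad - k + stride) / stride);
          const int oh_hi = std::min(Ho - 1, (h + pad) / stride);
          for (int ow = ow_lo; ow <= ow_hi; ++ow) {
            const int kj = wcol + pad - ow * stride;
            for (int oh = oh_lo; oh <= oh_hi; ++oh) {
              const int ki = h + pad - oh * stride;
              const double* wrow = wp + ki + (size_t)k * kj + ktap * ci;
              double* yo = yt + oh + (size_t)Ho * ow;
              for (int co = 0; co < Cout; ++co) {
                yo[(size_t)co * Ho * Wo] += v * wrow[ktap * Cin * co];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Weight gradient for the sparse input path: gW[ki,kj,ci,co] accumulates
// x[h,w,ci,t] * gy[oh,ow,co,t] over the same compatible pairs.
// [[Rcpp::export]]
NumericVector conv2d_bwd_w_sparse(NumericVector x, NumericVector gy,
                                  int stride, int pad, int k) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dg = gy.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], T = dx[3];
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2];
  if (dg[3] != T) stop("conv2d_bwd_w_sparse: frame count mismatch");
  NumericVector gw((size_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  double* gp = &gw[0];
  const size_t ktap = (size_t)k * k;
  for (int t = 0; t < T; ++t) {
    const double* xt = &x[0] + (size_t)t * H * W * Cin;
    const double* gt = &gy[0] + (size_t)t * Ho * Wo * Cout;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xt + (size_t)ci * H * W;
      for (int wcol = 0; wcol < W; ++wcol) {
        const int ow_lo = std::max(0, (wcol + pad - k + stride) / stride);
        const int ow_hi = std::min(Wo - 1, (wcol + pad) / stride);
        for (int h = 0; h < H; ++h) {
          const double v = xc[h + (size_t)wcol * H];
          if (v == 0.0) continue;
          const int oh_lo = std::max(0, (h + pad - k + stride) / stride);
          const int oh_hi = std::min(Ho - 1, (h + pad) / stride);
          for (int ow = ow_lo; ow <= ow_hi; ++ow) {
            const int kj = wcol + pad - ow * stride;
            for (int oh = oh_lo; oh <= oh_hi; ++oh) {
              const int ki = h + pad - oh * stride;
              double* grow = gp + ki + (size_t)k * kj + ktap * ci;
              const double* go = gt + oh + (size_t)Ho * ow;
              for (int co = 0; co < Cout; ++co) {
                grow[ktap * Cin * co] += v * go[(size_t)co * Ho * Wo];
              }
            }
          }
        }
      }
    }
  }
  return gw;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, int stride,
                         int pad) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], T = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) stop("conv2d_fwd: weight shape mismatch");
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * Cout * T);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, T);
  arma::mat Wm(const_cast<double*>(&w[0]), (size_t)k * k * Cin, Cout, false);
  arma::mat M((size_t)Ho * Wo, (size_t)k * k * Cin);
  for (int t = 0; t < T; ++t) {
    const double* xt = &x[0] + (size_t)t * H * W * Cin;
    im2col_frame(xt, H, W, Cin, k, stride, pad, M);
    arma::mat Y(&y[0] + (size_t)t * Ho * Wo * Cout, (size_t)Ho * Wo, Cout,
                false, true);
    Y = M * Wm;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_w(NumericVector x, NumericVector gy, int stride,
                           int pad, int k) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dg = gy.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], T = dx[3];
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2];
  if (dg[3] != T) stop("conv2d_bwd_w: frame count mismatch");
  NumericVector gw((size_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  arma::mat GW(&gw[0], (size_t)k * k * Cin, Cout, false, true);
  arma::mat M((size_t)Ho * Wo, (size_t)k * k * Cin);
  for (int t = 0; t < T; ++t) {
    const double* xt = &x[0] + (size_t)t * H * W * Cin;
    im2col_frame(xt, H, W, Cin, k, stride, pad, M);
    arma::mat GY(const_cast<double*>(&gy[0]) + (size_t)t * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false);
    GW += M.t() * GY;
  }
  return gw;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_x(NumericVector gy, NumericVector w, int stride,
                           int pad, int H, int W) {
  IntegerVector dg = gy.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int Ho = dg[0], Wo = dg[1], Cout = dg[2], T = dg[3];
  const int k = dw[0], Cin = dw[2];
  if (dw[3] != Cout) stop("conv2d_bwd_x: weight shape mismatch");
  NumericVector gx((size_t)H * W * Cin * T);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, T);
  arma::mat Wm(const_cast<double*>(&w[0]), (size_t)k * k * Cin, Cout, false);
  for (int t = 0; t < T; ++t) {
    arma::mat GY(const_cast<double*>(&gy[0]) + (size_t)t * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false);
    arma::mat Gcol = GY * Wm.t();  // (Ho*Wo) x (k*k*Cin)
    double* gxt = &gx[0] + (size_t)t * H * W * Cin;
    for (int c = 0; c < Cin; ++c) {
      double* gxc = gxt + (size_t)c * H * W;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int q = ki + k * (kj + k * c);
          const double* col = Gcol.colptr(q);
          for (int ow = 0; ow < Wo; ++ow) {
            const int wcol = ow * stride - pad + kj;
            if (wcol < 0 || wcol >= W) continue;
            const double* src = col + (size_t)ow * Ho;
            double* dst = gxc + (size_t)wcol * H;
            for (int oh = 0; oh < Ho; ++oh) {
              const int h = oh * stride - pad + ki;
              if (h >= 0 && h < H) dst[h] += src[oh];
            }
          }
        }
      }
    }
  }
  return gx;
}

// Leaky-integrator chain over time: u_t = a u_{t-1} + (1 - a) z_t, u_0- = 0.
// z is (n, T) with one column per timestep.
// [[Rcpp::export]]
NumericMatrix li_chain_fwd(NumericMatrix z, double a) {
  const int n = z.nrow(), T = z.ncol();
  NumericMatrix u(n, T);
  for (int t = 0; t < T; ++t) {
    const double* zt = &z[0] + (size_t)t * n;
    double* ut = &u[0] + (size_t)t * n;
    if (t == 0) {
      for (int i = 0; i < n; ++i) ut[i] = (1 - a) * zt[i];
    } else {
      const double* up = ut - n;
      for (int i = 0; i < n; ++i) ut[i] = a * up[i] + (1 - a) * zt[i];
    }
  }
  return u;
}

// Backward pass of the chain. gin is the external gradient dL/du at each
// step; returns gz = dL/dz and ga = dL/da (for trainable time constants).
// [[Rcpp::export]]
List li_chain_bwd(NumericMatrix gin, NumericMatrix u, NumericMatrix z,
                  double a) {
  const int n = gin.nrow(), T = gin.ncol();
  NumericMatrix gz(n, T);
  std::vector<double> gu(n, 0.0);
  double ga = 0.0;
  for (int t = T - 1; t >= 0; --t) {
    const double* gt = &gin[0] + (size_t)t * n;
    const double* zt = &z[0] + (size_t)t * n;
    const double* up = (t > 0) ? (&u[0] + (size_t)(t - 1) * n) : nullptr;
    double* gzt = &gz[0] + (size_t)t * n;
    for (int i = 0; i < n; ++i) {
      const double g = gt[i] + a * gu[i];
      gzt[i] = (1 - a) * g;
      ga += g * ((up ? up[i] : 0.0) - zt[i]);
      gu[i] = g;
    }
  }
  return List::create(Named("gz") = gz, Named("ga") = ga);
}
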