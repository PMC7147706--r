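// Low-level CNN kernels: 2-D convolution (im2col + GEMM), 2x2/stride-2
// transposed convolution, 3x3 max pooling, batch normalization, ReLU and
// channel concatenation, each with its backward pass. Tensors are R arrays in
// (H, W, C, N) column-major layout; weights are (kh, kw, Cin, Cout). The
// im2col buffer is laid out (Ho*Wo) x (kh*kw*Cin) so that building it is a
// series of contiguous column-segment copies and the GEMM needs no transpose.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// Kt(col r = ki + kh*kj + kh*kw*ci, row = ho + Ho*wo); zero padding.
static void im2col_t(const double* x, int H, int W, int C,
                     int kh, int kw, int stride, int pad,
                     int Ho, int Wo, double* Kt) {
  const size_t HoWo = (size_t)Ho * Wo;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* col = Kt + ((size_t)ci * kh * kw + (size_t)kj * kh + ki) * HoWo;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          double* dst = col + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* sc = xc + (size_t)wi * H;
          const int hi0 = -pad + ki;  // input row for ho = 0
          if (stride == 1) {
            // contiguous run with clamped ends
            int ho_lo = std::max(0, -hi0);
            int ho_hi = std::min(Ho, H - hi0);
            if (ho_lo > 0) std::fill(dst, dst + ho_lo, 0.0);
            if (ho_hi < ho_lo) ho_hi = ho_lo;
            if (ho_hi > ho_lo)
              std::copy(sc + hi0 + ho_lo, sc + hi0 + ho_hi, dst + ho_lo);
            if (ho_hi < Ho) std::fill(dst + ho_hi, dst + Ho, 0.0);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + hi0;
              dst[ho] = (hi >= 0 && hi < H) ? sc[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col_t
static void col2im_t_add(const double* Kt, int H, int W, int C,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo, double* x) {
  const size_t HoWo = (size_t)Ho * Wo;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* col =
            Kt + ((size_t)ci * kh * kw + (size_t)kj * kh + ki) * HoWo;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* sc = xc + (size_t)wi * H;
          const double* src = col + (size_t)wo * Ho;
          const int hi0 = -pad + ki;
          if (stride == 1) {
            const int ho_lo = std::max(0, -hi0);
            const int ho_hi = std::min(Ho, H - hi0);
            for (int ho = ho_lo; ho < ho_hi; ++ho) sc[hi0 + ho] += src[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + hi0;
              if (hi >= 0 && hi < H) sc[hi] += src[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  const bool one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat Kt;
  if (!one) Kt.set_size((size_t)Ho * Wo, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xi = x.begin() + (size_t)n * H * W * C;
    arma::mat Ym(y.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout,
                 false, true);
    if (one) {
      const arma::mat Xm(const_cast<double*>(xi), (size_t)H * W, C, false,
                         true);
      Ym = Xm * Wm;
    } else {
      im2col_t(xi, H, W, C, kh, kw, stride, pad, Ho, Wo, Kt.memptr());
      Ym = Kt * Wm;
    }
    Ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int gd[4]; dims4(gy, gd);
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(Rf_allocVector(REALSXP, w.size()));
  std::fill(gw.begin(), gw.end(), 0.0);
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat gWm(gw.begin(), kh * kw * Cin, Cout, false, true);
  arma::rowvec gbv(gb.begin(), Cout, false, true);
  const bool one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat Kt, gKt;
  if (!one) {
    Kt.set_size((size_t)Ho * Wo, kh * kw * Cin);
    gKt.set_size((size_t)Ho * Wo, kh * kw * Cin);
  }
  for (int n = 0; n < N; ++n) {
    const double* xi = x.begin() + (size_t)n * H * W * C;
    arma::mat gYm(gy.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo,
                  Cout, false, true);
    gbv += arma::sum(gYm, 0);
    if (one) {
      const arma::mat Xm(const_cast<double*>(xi), (size_t)H * W, C, false,
                         true);
      arma::mat gXm(gx.begin() + (size_t)n * H * W * C, (size_t)H * W, C,
                    false, true);
      gWm += Xm.t() * gYm;
      gXm += gYm * Wm.t();
    } else {
      im2col_t(xi, H, W, C, kh, kw, stride, pad, Ho, Wo, Kt.memptr());
      gWm += Kt.t() * gYm;
      gKt = gYm * Wm.t();
      col2im_t_add(gKt.memptr(), H, W, C, kh, kw, stride, pad, Ho, Wo,
                   gx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// contiguous Cin x Cout weight matrix for one (di, dj) tap of a 2x2 kernel
static arma::mat tap_matrix(const NumericVector& w, int di, int dj,
                            int Cin, int Cout) {
  arma::mat M(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      M(ci, co) = w[di + 2 * dj + 4 * (ci + (size_t)Cin * co)];
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Ydd((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const arma::mat Xm(x.begin() + (size_t)n * H * W * C, (size_t)H * W, C,
                       false, true);
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const arma::mat Wdd = tap_matrix(w, di, dj, Cin, Cout);
        Ydd = Xm * Wdd;
        for (int co = 0; co < Cout; ++co) {
          const double bias = b[co];
          for (int wcol = 0; wcol < W; ++wcol) {
            double* dst = yn + (size_t)co * Ho * Wo +
                          (size_t)(2 * wcol + dj) * Ho + di;
            const double* src = Ydd.colptr(co) + (size_t)wcol * H;
            for (int h = 0; h < H; ++h) dst[2 * h] = src[h] + bias;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(Rf_allocVector(REALSXP, w.size()));
  std::fill(gw.begin(), gw.end(), 0.0);
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  arma::mat gYdd((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const arma::mat Xm(x.begin() + (size_t)n * H * W * C, (size_t)H * W, C,
                       false, true);
    arma::mat gXm(gx.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false,
                  true);
    const double* gyn = gy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        for (int co = 0; co < Cout; ++co) {
          double* dst = gYdd.colptr(co);
          for (int wcol = 0; wcol < W; ++wcol) {
            const double* src = gyn + (size_t)co * Ho * Wo +
                                (size_t)(2 * wcol + dj) * Ho + di;
            for (int h = 0; h < H; ++h) dst[wcol * (size_t)H + h] = src[2 * h];
          }
        }
        const arma::mat Wdd = tap_matrix(w, di, dj, Cin, Cout);
        gXm += gYdd * Wdd.t();
        const arma::mat gWdd = Xm.t() * gYdd;
        for (int co = 0; co < Cout; ++co) {
          gb[co] += arma::accu(gYdd.col(co));
          for (int ci = 0; ci < Cin; ++ci)
            gw[di + 2 * dj + 4 * (ci + (size_t)Cin * co)] += gWdd(ci, co);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector am(y.size());
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      const R_xlen_t base = (R_xlen_t)(n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[(size_t)wi * H + hi];
              if (v > best) { best = v; bidx = wi * H + hi; }
            }
          }
          const R_xlen_t oidx = o + (R_xlen_t)wo * Ho + ho;
          y[oidx] = best;
          am[oidx] = (int)(base + bidx);
        }
      }
      o += (R_xlen_t)Ho * Wo;
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector argmax, NumericVector gy,
                              IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(Rf_allocVector(REALSXP, n));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, double momentum,
                bool training, double eps) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  NumericVector bm(C), biv(C), nrm(C), nrv(C);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double M = (double)HW * N;
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      nrm[c] = momentum * rmean[c] + (1 - momentum) * m;
      nrv[c] = momentum * rvar[c] + (1 - momentum) * v;
    } else {
      m = rmean[c]; v = rvar[c];
      nrm[c] = rmean[c]; nrv[c] = rvar[c];
    }
    const double invstd = 1.0 / std::sqrt(v + eps);
    bm[c] = m; biv[c] = invstd;
    const double g = gamma[c] * invstd, b0 = beta[c] - gamma[c] * invstd * m;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      double* q = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) q[i] = g * p[i] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = bm, _["invstd"] = biv,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
                NumericVector invstd, NumericVector gy) {
  int d[4]; dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = x.attr("dim");
  NumericVector gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], is = invstd[c];
    double sgy = 0, sgyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((size_t)n * C + c) * HW;
      const double* pg = gy.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        sgy += pg[i];
        sgyx += pg[i] * (px[i] - m) * is;
      }
    }
    gg[c] = sgyx; gb[c] = sgy;
    const double k1 = gamma[c] * is;
    const double c1 = sgy / M, c2 = sgyx / M;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((size_t)n * C + c) * HW;
      const double* pg = gy.begin() + ((size_t)n * C + c) * HW;
      double* pq = gx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        pq[i] = k1 * (pg[i] - c1 - (px[i] - m) * is * c2);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector x, NumericVector gy) {
  NumericVector gx(Rf_allocVector(REALSXP, x.size()));
  gx.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  const double* g = gy.begin();
  double* q = gx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? g[i] : 0.0;
  return gx;
}

// channel-wise concatenation of two (H, W, C, N) arrays
// [[Rcpp::export]]
NumericVector cpp_concat2(NumericVector a, NumericVector b) {
  int da[4]; dims4(a, da);
  int db[4]; dims4(b, db);
  if (da[0] != db[0] || da[1] != db[1] || da[3] != db[3]) {
    stop("concat: spatial/batch dimensions differ");
  }
  const size_t HW = (size_t)da[0] * da[1];
  const int Ca = da[2], Cb = db[2], N = da[3];
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HW * (Ca + Cb) * N));
  y.attr("dim") = IntegerVector::create(da[0], da[1], Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + (size_t)n * HW * Ca,
              a.begin() + (size_t)(n + 1) * HW * Ca,
              y.begin() + (size_t)n * HW * (Ca + Cb));
    std::copy(b.begin() + (size_t)n * HW * Cb,
              b.begin() + (size_t)(n + 1) * HW * Cb,
              y.begin() + (size_t)n * HW * (Ca + Cb) + HW * Ca);
  }
  return y;
}

// channels [from, to] (1-based, inclusive) of an (H, W, C, N) array
// [[Rcpp::export]]
NumericVector cpp_channel_slice(NumericVector x, int from, int to) {
  int d[4]; dims4(x, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3], Cs = to - from + 1;
  if (from < 1 || to > C || Cs < 1) stop("invalid channel slice");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HW * Cs * N));
  y.attr("dim") = IntegerVector::create(d[0], d[1], Cs, N);
  for (int n = 0; n < N; ++n) {
    std::copy(x.begin() + ((size_t)n * C + from - 1) * HW,
              x.begin() + ((size_t)n * C + to) * HW,
              y.begin() + (size_t)n * Cs * HW);
  }
  return y;
}
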