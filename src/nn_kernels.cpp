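// Low-level neural-network kernels.
//
// Tensor convention: 4-D arrays are stored as R arrays with dim
// (H, W, C, N) — column-major, so each sample is a contiguous
// H*W*C block and each channel a contiguous H*W block.
// Convolution weights are stored as (KH, KW, Cin, Cout), which in
// column-major order is directly the (KH*KW*Cin) x Cout matrix used
// by the im2col GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N), got %d dims", (int)d.size());
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample: x points to an (H, W, C) block.
// col has rows kh + KH*(kw + KW*c), cols ho + Hout*wo.
static void im2col(const double* x, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int Hout, int Wout, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int r = kh + KH * (kw + KW * c);
        double* colr = col.memptr() + r; // stride KH*KW*C between cols
        const int rowstride = KH * KW * C;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          const double* xcw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            colr[(size_t)(ho + Hout * wo) * rowstride] = xcw[hi];
          }
        }
      }
    }
  }
}

// scatter-add of a column matrix back to an (H, W, C) image block
static void col2im(const arma::mat& col, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int Hout, int Wout, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int r = kh + KH * (kw + KW * c);
        const double* colr = col.memptr() + r;
        const int rowstride = KH * KW * C;
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            xcw[hi] += colr[(size_t)(ho + Hout * wo) * rowstride];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias,
                                 int stride, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("conv weights must be (KH, KW, Cin, Cout)");
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  const int Hout = (H + 2 * pad - KH) / stride + 1;
  const int Wout = (W + 2 * pad - KW) / stride + 1;
  if (Hout < 1 || Wout < 1) stop("conv2d: output size would be empty");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)KH * KW * Cin, Cout, false, true);
  NumericVector out((size_t)Hout * Wout * Cout * N);
  out.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);

  arma::rowvec bvec;
  bool has_b = bias.isNotNull();
  if (has_b) {
    NumericVector b(bias);
    bvec = arma::rowvec(b.begin(), Cout);
  }

  arma::mat col((size_t)KH * KW * Cin, (size_t)Hout * Wout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad, Hout, Wout, col);
    // (Hout*Wout) x Cout, column-major == output memory layout
    arma::mat o = col.t() * Wm;
    if (has_b) o.each_row() += bvec;
    std::copy(o.begin(), o.end(), out.begin() + (size_t)n * Hout * Wout * Cout);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad, bool has_bias, bool need_gx) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  int Hout, Wout, Cg, Ng; get_dims4(gout, Hout, Wout, Cg, Ng);
  if (Cg != Cout || Ng != N) stop("conv2d backward: gradient shape mismatch");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)KH * KW * Cin, Cout, false, true);
  arma::mat gW((size_t)KH * KW * Cin, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);

  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  arma::mat col((size_t)KH * KW * Cin, (size_t)Hout * Wout);
  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)n * Hout * Wout * Cout,
                (size_t)Hout * Wout, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad, Hout, Wout, col);
    gW += col * G;
    if (has_bias) gb += arma::sum(G, 0);
    if (need_gx) {
      arma::mat gcol = Wm * G.t();
      col2im(gcol, H, W, C, KH, KW, stride, pad, Hout, Wout,
             gx.begin() + (size_t)n * H * W * C);
    }
  }

  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = IntegerVector::create(KH, KW, Cin, Cout);
  List res = List::create(_["gw"] = gWr);
  if (has_bias) res["gb"] = NumericVector(gb.begin(), gb.end());
  if (need_gx) res["gx"] = gx;
  return res;
}

// [[Rcpp::export(rng = false)]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)Hout * Wout * C * N);
  out.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  IntegerVector arg((size_t)Hout * Wout * C * N); // linear index into the (H,W) plane
  arg.attr("dim") = IntegerVector::create(Hout, Wout, C, N);

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* oc = out.begin() + ((size_t)n * C + c) * Hout * Wout;
      int* ac = arg.begin() + ((size_t)n * C + c) * Hout * Wout;
      for (int wo = 0; wo < Wout; ++wo) {
        for (int ho = 0; ho < Hout; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (size_t)wi * H];
              if (v > best) { best = v; besti = hi + wi * H; }
            }
          }
          oc[ho + (size_t)wo * Hout] = best;
          ac[ho + (size_t)wo * Hout] = besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_maxpool_backward(NumericVector gout, IntegerVector argmax,
                                   int H, int W) {
  int Hout, Wout, C, N; get_dims4(gout, Hout, Wout, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t po = ((size_t)n * C + c) * Hout * Wout;
      const size_t pi = ((size_t)n * C + c) * H * W;
      for (size_t j = 0; j < (size_t)Hout * Wout; ++j) {
        gx[pi + argmax[po + j]] += gout[po + j];
      }
    }
  }
  return gx;
}

// Batch norm over (H, W, N) per channel.
// [[Rcpp::export(rng = false)]]
List cpp_bn2d_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector run_mean, NumericVector run_var,
                      bool training, double momentum, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;

  NumericVector out((size_t)plane * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector mean(C), var(C), new_rm(C), new_rv(C);

  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * plane;
        for (size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      const double mu = s / m;
      double v = s2 / m - mu * mu;
      if (v < 0) v = 0;
      mean[c] = mu; var[c] = v;
      const double unbias = m > 1 ? m / (m - 1) : 1.0;
      new_rm[c] = (1 - momentum) * run_mean[c] + momentum * mu;
      new_rv[c] = (1 - momentum) * run_var[c] + momentum * v * unbias;
    }
  } else {
    for (int c = 0; c < C; ++c) { mean[c] = run_mean[c]; var[c] = run_var[c]; }
    new_rm = run_mean; new_rv = run_var;
  }

  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], mu = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * plane;
      double* oc = out.begin() + ((size_t)n * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) oc[i] = g * (xc[i] - mu) * inv + b;
    }
  }
  return List::create(_["out"] = out, _["mean"] = mean, _["var"] = var,
                      _["run_mean"] = new_rm, _["run_var"] = new_rv);
}

// [[Rcpp::export(rng = false)]]
List cpp_bn2d_backward(NumericVector x, NumericVector gout, NumericVector gamma,
                       NumericVector mean, NumericVector var, double eps,
                       bool training) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;

  NumericVector gx((size_t)plane * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);

  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double mu = mean[c];
    double sg = 0, sgx = 0; // sum g, sum g*xhat
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * plane;
      const double* gc = gout.begin() + ((size_t)n * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) {
        const double xh = (xc[i] - mu) * inv;
        sg += gc[i];
        sgx += gc[i] * xh;
      }
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double g = gamma[c];
    if (training) {
      const double mg = sg / m, mgx = sgx / m;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * plane;
        const double* gc = gout.begin() + ((size_t)n * C + c) * plane;
        double* oc = gx.begin() + ((size_t)n * C + c) * plane;
        for (size_t i = 0; i < plane; ++i) {
          const double xh = (xc[i] - mu) * inv;
          oc[i] = g * inv * (gc[i] - mg - xh * mgx);
        }
      }
    } else {
      // frozen statistics: the transform is affine per channel
      for (int n = 0; n < N; ++n) {
        const double* gc = gout.begin() + ((size_t)n * C + c) * plane;
        double* oc = gx.begin() + ((size_t)n * C + c) * plane;
        for (size_t i = 0; i < plane; ++i) oc[i] = g * inv * gc[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Bilinear sampler: map output pixel (r, c) through the affine
// [a11 a12 t1; a21 a22 t2] (in input pixel coordinates, 0-based) and
// sample the (H, W, C) input with border replication.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_affine_sample(NumericVector x, int Hout, int Wout,
                                NumericVector A) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("affine sample expects (H, W, C)");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)Hout * Wout * C);
  out.attr("dim") = IntegerVector::create(Hout, Wout, C);
  const double a11 = A[0], a21 = A[1], a12 = A[2], a22 = A[3], t1 = A[4], t2 = A[5];
  for (int co = 0; co < Wout; ++co) {
    for (int ro = 0; ro < Hout; ++ro) {
      double ri = a11 * ro + a12 * co + t1;
      double ci = a21 * ro + a22 * co + t2;
      if (ri < 0) ri = 0; if (ri > H - 1) ri = H - 1;
      if (ci < 0) ci = 0; if (ci > W - 1) ci = W - 1;
      const int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
      const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      const double fr = ri - r0, fc = ci - c0;
      for (int ch = 0; ch < C; ++ch) {
        const double* xc = x.begin() + (size_t)ch * H * W;
        const double v00 = xc[r0 + (size_t)c0 * H], v10 = xc[r1 + (size_t)c0 * H];
        const double v01 = xc[r0 + (size_t)c1 * H], v11 = xc[r1 + (size_t)c1 * H];
        out[ro + (size_t)co * Hout + (size_t)ch * Hout * Wout] =
          (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
      }
    }
  }
  return out;
}
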