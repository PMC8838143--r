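// Low-level tensor kernels for the LCNet engine.
//
// Activation tensors are R arrays with dim (H, W, C, B), column-major, double.
// Convolution weights have dim (k, k, Cin, Cout); flattened column-major this
// is exactly the (k*k*Cin) x Cout matrix used in the im2col GEMM, so weight
// memory is aliased, never copied.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d (H, W, C, B) array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col (transposed layout) for one image: x (H,W,C) at base pointer,
// zero padding. colT is (Ho*Wo) x (k*k*C); column r = i + k*j + k*k*c maps
// to kernel offset (i=dy, j=dx) and input channel c; row q = ho + Ho*wo.
// Writes run contiguously down each column (ho fastest).
static void im2colT(const double* x, int H, int W, int C,
                    int k, int stride, int pad, int Ho, int Wo,
                    arma::mat& colT) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        double* dst = colT.colptr(i + k * j + (size_t)k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          double* d0 = dst + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(d0, d0 + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          if (stride == 1 && pad == 0) {
            std::copy(xcol + i, xcol + i + Ho, d0);
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + i;
              d0[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2colT
static void col2imT(const arma::mat& colT, int H, int W, int C,
                    int k, int stride, int pad, int Ho, int Wo,
                    double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const double* src = colT.colptr(i + k * j + (size_t)k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* s0 = src + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi >= 0 && hi < H) xcol[hi] += s0[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if (Cin != C) stop("channel mismatch in convolution");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  bool pointwise = (k == 1 && stride == 1 && pad == 0);

  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  NumericVector out((size_t)Ho * Wo * Cout * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);

  arma::mat colT;
  if (!pointwise) colT.set_size((size_t)Ho * Wo, (size_t)k * k * C);
  for (int bi = 0; bi < B; ++bi) {
    // y: (Ho*Wo) x Cout, column-major == (Ho,Wo,Cout) block of out
    arma::mat y(out.begin() + (size_t)bi * Ho * Wo * Cout,
                (size_t)Ho * Wo, Cout, false, true);
    if (pointwise) {
      // 1x1 stride-1: the col matrix is the input plane itself
      const arma::mat X(const_cast<double*>(x.begin()) + (size_t)bi * H * W * C,
                        (size_t)H * W, C, false, true);
      y = X * Wm;
    } else {
      im2colT(x.begin() + (size_t)bi * H * W * C, H, W, C, k, stride, pad,
              Ho, Wo, colT);
      y = colT * Wm;
    }
    y.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cout = wd[3];
  int dd[4]; get_dim4(dy, dd);
  int Ho = dd[0], Wo = dd[1];
  bool pointwise = (k == 1 && stride == 1 && pad == 0);

  arma::mat Wm(w.begin(), (size_t)k * k * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), (size_t)k * k * C, Cout, false, true);
  arma::vec db(Cout, arma::fill::zeros);

  arma::mat colT, dcolT;
  if (!pointwise) {
    colT.set_size((size_t)Ho * Wo, (size_t)k * k * C);
    dcolT.set_size((size_t)Ho * Wo, (size_t)k * k * C);
  }
  for (int bi = 0; bi < B; ++bi) {
    arma::mat Dy(dy.begin() + (size_t)bi * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    db += arma::sum(Dy, 0).t();
    if (pointwise) {
      const arma::mat X(const_cast<double*>(x.begin()) + (size_t)bi * H * W * C,
                        (size_t)H * W, C, false, true);
      arma::mat dX(dx.begin() + (size_t)bi * H * W * C,
                   (size_t)H * W, C, false, true);
      dWm += X.t() * Dy;
      dX = Dy * Wm.t();
    } else {
      const double* xb = x.begin() + (size_t)bi * H * W * C;
      im2colT(xb, H, W, C, k, stride, pad, Ho, Wo, colT);
      dWm += colT.t() * Dy;
      dcolT = Dy * Wm.t();
      col2imT(dcolT, H, W, C, k, stride, pad, Ho, Wo,
              dx.begin() + (size_t)bi * H * W * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Channel-wise concatenation of (H,W,Ci,B) arrays.
// [[Rcpp::export]]
NumericVector cpp_concat_channels(List xs) {
  int n = xs.size();
  std::vector<NumericVector> v(n);
  int H = 0, W = 0, B = 0, Ctot = 0;
  std::vector<int> Cs(n);
  for (int i = 0; i < n; ++i) {
    v[i] = as<NumericVector>(xs[i]);
    int d[4]; get_dim4(v[i], d);
    if (i == 0) { H = d[0]; W = d[1]; B = d[3]; }
    else if (d[0] != H || d[1] != W || d[3] != B)
      stop("concatenation inputs differ in spatial or batch size");
    Cs[i] = d[2]; Ctot += d[2];
  }
  NumericVector out((size_t)H * W * Ctot * B);
  out.attr("dim") = IntegerVector::create(H, W, Ctot, B);
  size_t plane = (size_t)H * W;
  for (int bi = 0; bi < B; ++bi) {
    double* obase = out.begin() + (size_t)bi * plane * Ctot;
    size_t off = 0;
    for (int i = 0; i < n; ++i) {
      const double* src = v[i].begin() + (size_t)bi * plane * Cs[i];
      std::copy(src, src + plane * Cs[i], obase + off);
      off += plane * Cs[i];
    }
  }
  return out;
}

// Slice channels [c0, c0+nc) of a (H,W,C,B) array (c0 is 0-based).
// [[Rcpp::export]]
NumericVector cpp_slice_channels(NumericVector x, int c0, int nc) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  NumericVector out((size_t)H * W * nc * B);
  out.attr("dim") = IntegerVector::create(H, W, nc, B);
  size_t plane = (size_t)H * W;
  for (int bi = 0; bi < B; ++bi) {
    const double* src = x.begin() + ((size_t)bi * C + c0) * plane;
    std::copy(src, src + plane * nc,
              out.begin() + (size_t)bi * plane * nc);
  }
  return out;
}

// 2x2 stride-2 max pooling; idx holds the 0-based offset of the argmax
// within the input array so the backward pass is a plain scatter.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  NumericVector idx(y.size());
  size_t q = 0;
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)bi * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t p00 = base + (size_t)(2 * wo) * H + 2 * ho;
          size_t best = p00; double v = x[p00];
          size_t cand[3] = {p00 + 1, p00 + (size_t)H, p00 + (size_t)H + 1};
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > v) { v = x[cand[t]]; best = cand[t]; }
          // y is (Ho,Wo,C,B): position ho + Ho*wo within channel plane
          q = base / 4 + (size_t)wo * Ho + ho;
          y[q] = v; idx[q] = (double)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector idx, NumericVector dy,
                               IntegerVector dimx) {
  NumericVector dx((size_t)dimx[0] * dimx[1] * dimx[2] * dimx[3]);
  dx.attr("dim") = dimx;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[(size_t)idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)bi * C + c) * H * W;
      size_t obase = base / 4;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t p = base + (size_t)(2 * wo) * H + 2 * ho;
          y[obase + (size_t)wo * Ho + ho] =
            0.25 * (x[p] + x[p + 1] + x[p + H] + x[p + H + 1]);
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector dy, IntegerVector dimx) {
  int H = dimx[0], W = dimx[1], C = dimx[2], B = dimx[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = dimx;
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)bi * C + c) * H * W;
      size_t obase = base / 4;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = 0.25 * dy[obase + (size_t)wo * Ho + ho];
          size_t p = base + (size_t)(2 * wo) * H + 2 * ho;
          dx[p] += g; dx[p + 1] += g; dx[p + H] += g; dx[p + H + 1] += g;
        }
    }
  return dx;
}

// Batch normalization over (H, W, B) per channel.
// training: use batch statistics (biased variance); else use supplied moments.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mean_in, NumericVector var_in,
                double eps, bool training) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  size_t plane = (size_t)H * W;
  NumericVector mu(C), va(C);
  if (training) {
    double n = (double)plane * B;
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int bi = 0; bi < B; ++bi) {
        const double* p = x.begin() + ((size_t)bi * C + c) * plane;
        for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu[c] = s / n;
      va[c] = s2 / n - mu[c] * mu[c];
      if (va[c] < 0) va[c] = 0;
    }
  } else { mu = mean_in; va = var_in; }

  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(va[c] + eps);
    double off = beta[c] - mu[c] * inv;
    for (int bi = 0; bi < B; ++bi) {
      const double* p = x.begin() + ((size_t)bi * C + c) * plane;
      double* q = y.begin() + ((size_t)bi * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) q[i] = p[i] * inv + off;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = va);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma,
                NumericVector mu, NumericVector va,
                double eps, NumericVector dy) {
  int d[4]; get_dim4(x, d);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  size_t plane = (size_t)H * W;
  double n = (double)plane * B;
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double istd = 1.0 / std::sqrt(va[c] + eps);
    double sdy = 0.0, sdyx = 0.0;
    for (int bi = 0; bi < B; ++bi) {
      const double* px = x.begin() + ((size_t)bi * C + c) * plane;
      const double* pd = dy.begin() + ((size_t)bi * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) {
        sdy += pd[i];
        sdyx += pd[i] * (px[i] - mu[c]) * istd;
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    double k1 = gamma[c] * istd / n;
    for (int bi = 0; bi < B; ++bi) {
      const double* px = x.begin() + ((size_t)bi * C + c) * plane;
      const double* pd = dy.begin() + ((size_t)bi * C + c) * plane;
      double* pq = dx.begin() + ((size_t)bi * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) {
        double xh = (px[i] - mu[c]) * istd;
        pq[i] = k1 * (n * pd[i] - sdy - xh * sdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] >= 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector x, NumericVector dy, double slope) {
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    dx[i] = x[i] >= 0 ? dy[i] : slope * dy[i];
  return dx;
}

// Bilinear sample of img (H,W,C) at continuous index-space point (ri, ci)
// with border replication.
static inline double sample_clamped(const double* ch, int H, int W,
                                    double ri, double ci) {
  if (ri < 0) ri = 0; if (ri > H - 1) ri = H - 1;
  if (ci < 0) ci = 0; if (ci > W - 1) ci = W - 1;
  int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
  int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
  double fr = ri - r0, fc = ci - c0;
  double top = ch[r0 + (size_t)c0 * H] * (1 - fc) + ch[r0 + (size_t)c1 * H] * fc;
  double bot = ch[r1 + (size_t)c0 * H] * (1 - fc) + ch[r1 + (size_t)c1 * H] * fc;
  return top * (1 - fr) + bot * fr;
}

// Half-pixel-centered bilinear resize of (H,W,C) to (target,target,C).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int target) {
  IntegerVector dm = img.attr("dim");
  int H = dm[0], W = dm[1], C = dm.size() >= 3 ? dm[2] : 1;
  NumericVector out((size_t)target * target * C);
  out.attr("dim") = IntegerVector::create(target, target, C);
  double sr = (double)H / target, sc = (double)W / target;
  for (int c = 0; c < C; ++c) {
    const double* ch = img.begin() + (size_t)c * H * W;
    double* oc = out.begin() + (size_t)c * target * target;
    for (int co = 0; co < target; ++co) {
      double ci = (co + 0.5) * sc - 0.5;
      for (int ro = 0; ro < target; ++ro) {
        double ri = (ro + 0.5) * sr - 0.5;
        oc[ro + (size_t)co * target] = sample_clamped(ch, H, W, ri, ci);
      }
    }
  }
  return out;
}

// Inverse-map affine resampling about pixel centers.
// m is the 2x3 output->input map in (x, y) center coordinates with the
// origin at the image center; out-of-range samples take fill[c].
// [[Rcpp::export]]
NumericVector cpp_affine_bilinear(NumericVector img, NumericMatrix m,
                                  NumericVector fill) {
  IntegerVector dm = img.attr("dim");
  int H = dm[0], W = dm[1], C = dm.size() >= 3 ? dm[2] : 1;
  NumericVector out(img.size()); out.attr("dim") = img.attr("dim");
  double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  for (int co = 0; co < W; ++co) {
    double xo = co - cx;
    for (int ro = 0; ro < H; ++ro) {
      double yo = ro - cy;
      double xi = m(0, 0) * xo + m(0, 1) * yo + m(0, 2) + cx;
      double yi = m(1, 0) * xo + m(1, 1) * yo + m(1, 2) + cy;
      bool inside = xi >= 0 && xi <= W - 1 && yi >= 0 && yi <= H - 1;
      for (int c = 0; c < C; ++c) {
        double v = inside
          ? sample_clamped(img.begin() + (size_t)c * H * W, H, W, yi, xi)
          : fill[c];
        out[ro + (size_t)co * H + (size_t)c * H * W] = v;
      }
    }
  }
  return out;
}
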