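#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are numeric arrays with dim c(H, W, N, C); element (h,w,n,c)
// sits at h + H*(w + W*(n + N*c)).  im2col emits a (Ho*Wo*N) x (k*k*C) matrix
// whose column q = ki + k*(kj + k*c) matches a kernel array of dim (k,k,Cin,Cout)
// flattened to a (k*k*Cin) x Cout matrix, so convolution is a single GEMM.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int M = Ho * Wo * N;
  NumericMatrix col(M, k * k * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        double* cp = &col(0, q);
        for (int n = 0; n < N; ++n) {
          const double* xbase = xp + (size_t)H * W * (n + (size_t)N * c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj;
            const bool w_ok = (w >= 0 && w < W);
            double* crow = cp + (size_t)Ho * (wo + (size_t)Wo * n);
            if (!w_ok) {
              for (int ho = 0; ho < Ho; ++ho) crow[ho] = 0.0;
            } else {
              const double* xc = xbase + (size_t)H * w;
              for (int ho = 0; ho < Ho; ++ho) {
                const int h = ho * stride - pad + ki;
                crow[ho] = (h >= 0 && h < H) ? xc[h] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& col, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((size_t)H * W * N * C);
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * (kj + k * c);
        const double* cp = &col(0, q);
        for (int n = 0; n < N; ++n) {
          double* dbase = dp + (size_t)H * W * (n + (size_t)N * c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            const double* crow = cp + (size_t)Ho * (wo + (size_t)Wo * n);
            double* dc = dbase + (size_t)H * w;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + ki;
              if (h >= 0 && h < H) dc[h] += crow[ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise convolution, one k x k kernel per channel (groups == C).
// wgt has dim (k, k, C).

// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(const NumericVector& x, const NumericVector& wgt,
                             int H, int W, int N, int C, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * N * C);
  const double* xp = x.begin();
  const double* wp = wgt.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = wp + (size_t)k * k * c;
    for (int n = 0; n < N; ++n) {
      const double* xb = xp + (size_t)H * W * (n + (size_t)N * c);
      double* yb = yp + (size_t)Ho * Wo * (n + (size_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              acc += xb[h + (size_t)H * w] * wc[ki + k * kj];
            }
          }
          yb[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(const NumericVector& dy, const NumericVector& x,
                    const NumericVector& wgt, int H, int W, int N, int C,
                    int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((size_t)H * W * N * C);
  NumericVector dw((size_t)k * k * C);
  const double* xp = x.begin();
  const double* wp = wgt.begin();
  const double* gp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = wp + (size_t)k * k * c;
    double* dwc = dwp + (size_t)k * k * c;
    for (int n = 0; n < N; ++n) {
      const double* xb = xp + (size_t)H * W * (n + (size_t)N * c);
      double* dxb = dxp + (size_t)H * W * (n + (size_t)N * c);
      const double* gb = gp + (size_t)Ho * Wo * (n + (size_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gb[ho + (size_t)Ho * wo];
          if (g == 0.0) continue;
          for (int kj = 0; kj < k; ++kj) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              dxb[h + (size_t)H * w] += g * wc[ki + k * kj];
              dwc[ki + k * kj] += g * xb[h + (size_t)H * w];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling with argmax indices (1-based linear indices into x) for backward.

// [[Rcpp::export]]
List maxpool_fwd_cpp(const NumericVector& x, int H, int W, int N, int C,
                     int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * N * C);
  IntegerVector idx((size_t)Ho * Wo * N * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const size_t xoff = (size_t)H * W * (n + (size_t)N * c);
      const double* xb = xp + xoff;
      const size_t yoff = (size_t)Ho * Wo * (n + (size_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              const double v = xb[h + (size_t)H * w];
              if (v > best) { best = v; besti = xoff + h + (size_t)H * w; }
            }
          }
          yp[yoff + ho + (size_t)Ho * wo] = best;
          ip[yoff + ho + (size_t)Ho * wo] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(const NumericVector& dy, const IntegerVector& idx,
                              R_xlen_t xlen) {
  NumericVector dx(xlen);
  const double* gp = dy.begin();
  const int* ip = idx.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dp[ip[i] - 1] += gp[i];
  return dx;
}

// Fused per-channel affine y = x * a[c] + b[c] over an (M, C) layout.

// [[Rcpp::export]]
NumericVector ch_affine_cpp(const NumericVector& x, const NumericVector& a,
                            const NumericVector& b, int M, int C) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = xp + (size_t)M * c;
    double* yc = yp + (size_t)M * c;
    for (int i = 0; i < M; ++i) yc[i] = xc[i] * ac + bc;
  }
  return y;
}

// Per-channel sums and sums of squares in one pass.

// [[Rcpp::export]]
List ch_stats_cpp(const NumericVector& x, int M, int C) {
  NumericVector s(C), ss(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)M * c;
    double acc = 0, acc2 = 0;
    for (int i = 0; i < M; ++i) { acc += xc[i]; acc2 += xc[i] * xc[i]; }
    s[c] = acc; ss[c] = acc2;
  }
  return List::create(_["sum"] = s, _["sumsq"] = ss);
}

// Fused batch-norm backward (training mode): given upstream grad g, input x,
// batch mean/inv-sd and gamma, returns dx, dgamma, dbeta.

// [[Rcpp::export]]
List bn_bwd_cpp(const NumericVector& g, const NumericVector& x,
                const NumericVector& mu, const NumericVector& inv_sd,
                const NumericVector& gamma, int M, int C, bool training) {
  NumericVector dx(g.size()), dgamma(C), dbeta(C);
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + (size_t)M * c;
    const double* xc = xp + (size_t)M * c;
    double* dc = dp + (size_t)M * c;
    const double m = mu[c], is = inv_sd[c], gm = gamma[c];
    double sg = 0, sgx = 0;
    for (int i = 0; i < M; ++i) {
      const double xh = (xc[i] - m) * is;
      sg += gc[i];
      sgx += gc[i] * xh;
    }
    dgamma[c] = sgx; dbeta[c] = sg;
    if (training) {
      const double mg = sg / M, mgx = sgx / M;
      for (int i = 0; i < M; ++i) {
        const double xh = (xc[i] - m) * is;
        dc[i] = gm * is * (gc[i] - mg - xh * mgx);
      }
    } else {
      for (int i = 0; i < M; ++i) dc[i] = gm * is * gc[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Fused SiLU forward / backward.

// [[Rcpp::export]]
NumericVector silu_fwd_cpp(const NumericVector& x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-xp[i]));
    yp[i] = xp[i] * s;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector silu_bwd_cpp(const NumericVector& g, const NumericVector& x) {
  NumericVector dx(x.size());
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-xp[i]));
    dp[i] = gp[i] * s * (1.0 + xp[i] * (1.0 - s));
  }
  return dx;
}

// Cache-friendly depthwise convolution: per (channel, image) slab, iterate
// kernel taps outermost with contiguous inner loops (stride 1 fast path).

// [[Rcpp::export]]
NumericVector dwconv_fwd2_cpp(const NumericVector& x, const NumericVector& wgt,
                              int H, int W, int N, int C, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * N * C);
  const double* xp = x.begin();
  const double* wp = wgt.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = wp + (size_t)k * k * c;
    for (int n = 0; n < N; ++n) {
      const double* xb = xp + (size_t)H * W * (n + (size_t)N * c);
      double* yb = yp + (size_t)Ho * Wo * (n + (size_t)N * c);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double wv = wc[ki + k * kj];
          if (wv == 0.0) continue;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            const double* xcol = xb + (size_t)H * w;
            double* ycol = yb + (size_t)Ho * wo;
            if (stride == 1) {
              int ho0 = std::max(0, pad - ki);
              int ho1 = std::min(Ho, H + pad - ki);
              const double* xs = xcol - pad + ki;
              for (int ho = ho0; ho < ho1; ++ho) ycol[ho] += wv * xs[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int h = ho * stride - pad + ki;
                if (h >= 0 && h < H) ycol[ho] += wv * xcol[h];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd2_cpp(const NumericVector& dy, const NumericVector& x,
                     const NumericVector& wgt, int H, int W, int N, int C,
                     int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((size_t)H * W * N * C);
  NumericVector dw((size_t)k * k * C);
  const double* xp = x.begin();
  const double* wp = wgt.begin();
  const double* gp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = wp + (size_t)k * k * c;
    double* dwc = dwp + (size_t)k * k * c;
    for (int n = 0; n < N; ++n) {
      const double* xb = xp + (size_t)H * W * (n + (size_t)N * c);
      double* dxb = dxp + (size_t)H * W * (n + (size_t)N * c);
      const double* gb = gp + (size_t)Ho * Wo * (n + (size_t)N * c);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double wv = wc[ki + k * kj];
          double acc = 0.0;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            const double* gcol = gb + (size_t)Ho * wo;
            const double* xcol = xb + (size_t)H * w;
            double* dxcol = dxb + (size_t)H * w;
            if (stride == 1) {
              int ho0 = std::max(0, pad - ki);
              int ho1 = std::min(Ho, H + pad - ki);
              const double* xs = xcol - pad + ki;
              double* dxs = dxcol - pad + ki;
              for (int ho = ho0; ho < ho1; ++ho) {
                acc += gcol[ho] * xs[ho];
                dxs[ho] += gcol[ho] * wv;
              }
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int h = ho * stride - pad + ki;
                if (h < 0 || h >= H) continue;
                acc += gcol[ho] * xcol[h];
                dxcol[h] += gcol[ho] * wv;
              }
            }
          }
          dwc[ki + k * kj] += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Orthonormal Haar analysis: (H, W, N, C) -> (H/2, W/2, N, 4C), bands
// stacked LL, LH, HL, HH on the channel axis (H, W even).

// [[Rcpp::export]]
NumericVector haar_fwd_cpp(const NumericVector& x, int H, int W, int N, int C) {
  const int h2 = H / 2, w2 = W / 2;
  const size_t band = (size_t)h2 * w2 * N;
  NumericVector y(band * 4 * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* xb = xp + (size_t)H * W * (n + (size_t)N * c);
      double* ll = yp + (size_t)h2 * w2 * (n + (size_t)N * c);
      double* lh = ll + band * C;
      double* hl = lh + band * C;
      double* hh = hl + band * C;
      for (int w = 0; w < w2; ++w) {
        const double* c1 = xb + (size_t)H * (2 * w);
        const double* c2 = c1 + H;
        const size_t off = (size_t)h2 * w;
        for (int h = 0; h < h2; ++h) {
          const double a = c1[2 * h], cc = c1[2 * h + 1];
          const double b = c2[2 * h], dd = c2[2 * h + 1];
          ll[off + h] = (a + b + cc + dd) * 0.5;
          lh[off + h] = (a - b + cc - dd) * 0.5;
          hl[off + h] = (a + b - cc - dd) * 0.5;
          hh[off + h] = (a - b - cc + dd) * 0.5;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector haar_inv_cpp(const NumericVector& b4, int h2, int w2, int N, int C) {
  const int H = 2 * h2, W = 2 * w2;
  const size_t band = (size_t)h2 * w2 * N;
  NumericVector y((size_t)H * W * N * C);
  const double* bp = b4.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* ll = bp + (size_t)h2 * w2 * (n + (size_t)N * c);
      const double* lh = ll + band * C;
      const double* hl = lh + band * C;
      const double* hh = hl + band * C;
      double* yb = yp + (size_t)H * W * (n + (size_t)N * c);
      for (int w = 0; w < w2; ++w) {
        double* c1 = yb + (size_t)H * (2 * w);
        double* c2 = c1 + H;
        const size_t off = (size_t)h2 * w;
        for (int h = 0; h < h2; ++h) {
          const double L = ll[off + h], Lh = lh[off + h];
          const double Hl = hl[off + h], Hh = hh[off + h];
          c1[2 * h]     = (L + Lh + Hl + Hh) * 0.5;
          c2[2 * h]     = (L - Lh + Hl - Hh) * 0.5;
          c1[2 * h + 1] = (L + Lh - Hl - Hh) * 0.5;
          c2[2 * h + 1] = (L - Lh - Hl + Hh) * 0.5;
        }
      }
    }
  }
  return y;
}

// Fused per-channel scale forward and backward.

// [[Rcpp::export]]
NumericVector ch_mul_cpp(const NumericVector& x, const NumericVector& s, int M, int C) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double sc = s[c];
    const double* xc = xp + (size_t)M * c;
    double* yc = yp + (size_t)M * c;
    for (int i = 0; i < M; ++i) yc[i] = xc[i] * sc;
  }
  return y;
}

// [[Rcpp::export]]
List ch_mul_bwd_cpp(const NumericVector& g, const NumericVector& x,
                    const NumericVector& s, int M, int C) {
  NumericVector dx(x.size()), ds(C);
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double sc = s[c];
    const double* xc = xp + (size_t)M * c;
    const double* gc = gp + (size_t)M * c;
    double* dc = dp + (size_t)M * c;
    double acc = 0.0;
    for (int i = 0; i < M; ++i) {
      dc[i] = gc[i] * sc;
      acc += gc[i] * xc[i];
    }
    ds[c] = acc;
  }
  return List::create(_["dx"] = dx, _["ds"] = ds);
}
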