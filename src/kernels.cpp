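#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Tensor layout everywhere: R array with dim = c(C, D, H, W), column-major,
// i.e. linear index = c + C*(z + D*(y + H*x)). Channels are contiguous so
// pointwise convolutions reduce to a single BLAS gemm on the R side.

static inline R_xlen_t idx4(int c, int z, int y, int x, int C, int D, int H) {
  return (R_xlen_t)c + (R_xlen_t)C * ((R_xlen_t)z + (R_xlen_t)D * ((R_xlen_t)y + (R_xlen_t)H * (R_xlen_t)x));
}

// Gather patches of x into a (C*kd*kh*kw) x nvox matrix for the output
// voxels with depth index in [z0, z1] (0-based, inclusive). Column order is
// zo fastest, then yo, then xo, matching the (C, D, H, W) array layout of
// the convolution output. Row order: c fastest, then tz, ty, tx.
// [[Rcpp::export]]
NumericMatrix cm_im2col3d(NumericVector x, IntegerVector xdim,
                          int kd, int kh, int kw,
                          int sd, int sh, int sw,
                          int pd, int ph, int pw,
                          int oh, int ow, int z0, int z1) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int nz = z1 - z0 + 1;
  const R_xlen_t nrow = (R_xlen_t)C * kd * kh * kw;
  const R_xlen_t ncol = (R_xlen_t)nz * oh * ow;
  NumericMatrix col((int)nrow, (int)ncol);
  double *pc = col.begin();
  const double *px = x.begin();
  for (int xo = 0; xo < ow; ++xo) {
    for (int yo = 0; yo < oh; ++yo) {
      for (int zo = z0; zo <= z1; ++zo) {
        R_xlen_t cidx = (R_xlen_t)(zo - z0) + (R_xlen_t)nz * ((R_xlen_t)yo + (R_xlen_t)oh * xo);
        double *dst = pc + cidx * nrow;
        for (int tx = 0; tx < kw; ++tx) {
          int xi = xo * sw - pw + tx;
          for (int ty = 0; ty < kh; ++ty) {
            int yi = yo * sh - ph + ty;
            for (int tz = 0; tz < kd; ++tz) {
              int zi = zo * sd - pd + tz;
              if (zi >= 0 && zi < D && yi >= 0 && yi < H && xi >= 0 && xi < W) {
                const double *src = px + idx4(0, zi, yi, xi, C, D, H);
                std::copy(src, src + C, dst);
              } else {
                std::fill(dst, dst + C, 0.0);
              }
              dst += C;
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add the column matrix back onto the x-shaped array `out`
// (accumulating); exact adjoint of cm_im2col3d with identical geometry.
// [[Rcpp::export]]
void cm_col2im3d(NumericMatrix col, NumericVector out, IntegerVector xdim,
                 int kd, int kh, int kw,
                 int sd, int sh, int sw,
                 int pd, int ph, int pw,
                 int oh, int ow, int z0, int z1) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int nz = z1 - z0 + 1;
  const R_xlen_t nrow = (R_xlen_t)C * kd * kh * kw;
  double *po = out.begin();
  const double *pc = col.begin();
  for (int xo = 0; xo < ow; ++xo) {
    for (int yo = 0; yo < oh; ++yo) {
      for (int zo = z0; zo <= z1; ++zo) {
        R_xlen_t cidx = (R_xlen_t)(zo - z0) + (R_xlen_t)nz * ((R_xlen_t)yo + (R_xlen_t)oh * xo);
        const double *src = pc + cidx * nrow;
        for (int tx = 0; tx < kw; ++tx) {
          int xi = xo * sw - pw + tx;
          for (int ty = 0; ty < kh; ++ty) {
            int yi = yo * sh - ph + ty;
            for (int tz = 0; tz < kd; ++tz) {
              int zi = zo * sd - pd + tz;
              if (zi >= 0 && zi < D && yi >= 0 && yi < H && xi >= 0 && xi < W) {
                double *dst = po + idx4(0, zi, yi, xi, C, D, H);
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
              src += C;
            }
          }
        }
      }
    }
  }
}

// Depthwise 3D convolution forward. w is (C, kd*kh*kw) with tap order
// tz fastest, then ty, tx (same as im2col rows within a channel block).
// [[Rcpp::export]]
NumericVector cm_dwconv3d_fwd(NumericVector x, IntegerVector xdim,
                              NumericMatrix w, NumericVector bias,
                              int kd, int kh, int kw,
                              int sd, int sh, int sw,
                              int pd, int ph, int pw) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int od = (D + 2 * pd - kd) / sd + 1;
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  NumericVector y((R_xlen_t)C * od * oh * ow);
  y.attr("dim") = IntegerVector::create(C, od, oh, ow);
  double *py = y.begin();
  const double *px = x.begin();
  const double *pw_ = w.begin();
  const double *pb = bias.begin();
  for (int xo = 0; xo < ow; ++xo) {
    for (int yo = 0; yo < oh; ++yo) {
      for (int zo = 0; zo < od; ++zo) {
        double *dst = py + idx4(0, zo, yo, xo, C, od, oh);
        for (int c = 0; c < C; ++c) dst[c] = pb[c];
        int tap = 0;
        for (int tx = 0; tx < kw; ++tx) {
          int xi = xo * sw - pw + tx;
          for (int ty = 0; ty < kh; ++ty) {
            int yi = yo * sh - ph + ty;
            for (int tz = 0; tz < kd; ++tz, ++tap) {
              int zi = zo * sd - pd + tz;
              if (zi < 0 || zi >= D || yi < 0 || yi >= H || xi < 0 || xi >= W) continue;
              const double *src = px + idx4(0, zi, yi, xi, C, D, H);
              const double *wv = pw_ + (R_xlen_t)tap * C;
              for (int c = 0; c < C; ++c) dst[c] += wv[c] * src[c];
            }
          }
        }
      }
    }
  }
  return y;
}

// Depthwise 3D convolution backward: returns grad wrt input, weights, bias.
// [[Rcpp::export]]
List cm_dwconv3d_bwd(NumericVector x, IntegerVector xdim,
                     NumericMatrix w, NumericVector gy,
                     int kd, int kh, int kw,
                     int sd, int sh, int sw,
                     int pd, int ph, int pw) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int od = (D + 2 * pd - kd) / sd + 1;
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  NumericVector gx((R_xlen_t)C * D * H * W);
  gx.attr("dim") = xdim;
  NumericMatrix gw(C, kd * kh * kw);
  NumericVector gb(C);
  double *pgx = gx.begin();
  double *pgw = gw.begin();
  double *pgb = gb.begin();
  const double *px = x.begin();
  const double *pw_ = w.begin();
  const double *pgy = gy.begin();
  for (int xo = 0; xo < ow; ++xo) {
    for (int yo = 0; yo < oh; ++yo) {
      for (int zo = 0; zo < od; ++zo) {
        const double *g = pgy + idx4(0, zo, yo, xo, C, od, oh);
        for (int c = 0; c < C; ++c) pgb[c] += g[c];
        int tap = 0;
        for (int tx = 0; tx < kw; ++tx) {
          int xi = xo * sw - pw + tx;
          for (int ty = 0; ty < kh; ++ty) {
            int yi = yo * sh - ph + ty;
            for (int tz = 0; tz < kd; ++tz, ++tap) {
              int zi = zo * sd - pd + tz;
              if (zi < 0 || zi >= D || yi < 0 || yi >= H || xi < 0 || xi >= W) continue;
              const double *src = px + idx4(0, zi, yi, xi, C, D, H);
              double *dgx = pgx + idx4(0, zi, yi, xi, C, D, H);
              const double *wv = pw_ + (R_xlen_t)tap * C;
              double *dgw = pgw + (R_xlen_t)tap * C;
              for (int c = 0; c < C; ++c) {
                dgx[c] += wv[c] * g[c];
                dgw[c] += src[c] * g[c];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2D median filter with a k x k window and replicate padding at borders.
// [[Rcpp::export]]
NumericMatrix cm_median2d(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol();
  const int r = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> win((size_t)k * k);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = std::min(std::max(j + dj, 0), W - 1);
        for (int di = -r; di <= r; ++di) {
          int ii = std::min(std::max(i + di, 0), H - 1);
          win[n++] = x(ii, jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + n / 2, win.begin() + n);
      out(i, j) = win[n / 2];
    }
  }
  return out;
}

// Direct (no im2col) small-channel 3D convolution forward.
// w is (Cout, Cin*kd*kh*kw) with rows contiguous (Cout fastest), matching
// the im2col weight layout.
// [[Rcpp::export]]
NumericVector cm_conv3d_direct_fwd(NumericVector x, IntegerVector xdim,
                                   NumericMatrix w, NumericVector bias,
                                   int cout,
                                   int kd, int kh, int kw,
                                   int sd, int sh, int sw,
                                   int pd, int ph, int pw) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int od = (D + 2 * pd - kd) / sd + 1;
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  NumericVector y((R_xlen_t)cout * od * oh * ow);
  y.attr("dim") = IntegerVector::create(cout, od, oh, ow);
  double *py = y.begin();
  const double *px = x.begin();
  const double *pw_ = w.begin();
  const double *pb = bias.begin();
  for (int xo = 0; xo < ow; ++xo) {
    for (int yo = 0; yo < oh; ++yo) {
      for (int zo = 0; zo < od; ++zo) {
        double *dst = py + idx4(0, zo, yo, xo, cout, od, oh);
        for (int co = 0; co < cout; ++co) dst[co] = pb[co];
        int col = 0;  // column of w = ci + C*(tz + kd*(ty + kh*tx))
        for (int tx = 0; tx < kw; ++tx) {
          int xi = xo * sw - pw + tx;
          for (int ty = 0; ty < kh; ++ty) {
            int yi = yo * sh - ph + ty;
            for (int tz = 0; tz < kd; ++tz) {
              int zi = zo * sd - pd + tz;
              if (zi < 0 || zi >= D || yi < 0 || yi >= H || xi < 0 || xi >= W) {
                col += C;
                continue;
              }
              const double *src = px + idx4(0, zi, yi, xi, C, D, H);
              for (int ci = 0; ci < C; ++ci, ++col) {
                const double v = src[ci];
                if (v == 0.0) continue;
                const double *wc = pw_ + (R_xlen_t)col * cout;
                for (int co = 0; co < cout; ++co) dst[co] += wc[co] * v;
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Direct small-channel conv backward: grads wrt input, weights, bias.
// [[Rcpp::export]]
List cm_conv3d_direct_bwd(NumericVector x, IntegerVector xdim,
                          NumericMatrix w, NumericVector gy,
                          int cout,
                          int kd, int kh, int kw,
                          int sd, int sh, int sw,
                          int pd, int ph, int pw) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int od = (D + 2 * pd - kd) / sd + 1;
  const int oh = (H + 2 * ph - kh) / sh + 1;
  const int ow = (W + 2 * pw - kw) / sw + 1;
  NumericVector gx((R_xlen_t)C * D * H * W);
  gx.attr("dim") = xdim;
  NumericMatrix gw(cout, C * kd * kh * kw);
  NumericVector gb(cout);
  double *pgx = gx.begin();
  double *pgw = gw.begin();
  double *pgb = gb.begin();
  const double *px = x.begin();
  const double *pw_ = w.begin();
  const double *pg = gy.begin();
  for (int xo = 0; xo < ow; ++xo) {
    for (int yo = 0; yo < oh; ++yo) {
      for (int zo = 0; zo < od; ++zo) {
        const double *g = pg + idx4(0, zo, yo, xo, cout, od, oh);
        for (int co = 0; co < cout; ++co) pgb[co] += g[co];
        int col = 0;
        for (int tx = 0; tx < kw; ++tx) {
          int xi = xo * sw - pw + tx;
          for (int ty = 0; ty < kh; ++ty) {
            int yi = yo * sh - ph + ty;
            for (int tz = 0; tz < kd; ++tz) {
              int zi = zo * sd - pd + tz;
              if (zi < 0 || zi >= D || yi < 0 || yi >= H || xi < 0 || xi >= W) {
                col += C;
                continue;
              }
              const double *src = px + idx4(0, zi, yi, xi, C, D, H);
              double *dgx = pgx + idx4(0, zi, yi, xi, C, D, H);
              for (int ci = 0; ci < C; ++ci, ++col) {
                const double *wc = pw_ + (R_xlen_t)col * cout;
                double *gwc = pgw + (R_xlen_t)col * cout;
                double acc = 0.0;
                const double v = src[ci];
                for (int co = 0; co < cout; ++co) {
                  acc += wc[co] * g[co];
                  gwc[co] += g[co] * v;
                }
                dgx[ci] += acc;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Fused training-mode batch norm over a (C, M) matrix view: per-channel
// mean/variance, normalized output, y = gamma * xhat + beta.
// [[Rcpp::export]]
List cm_bn_fwd(NumericVector x, int C, R_xlen_t M,
               NumericVector gamma, NumericVector beta, double eps) {
  NumericVector y(x.size());
  NumericVector xhat(x.size());
  NumericVector mu(C), var(C), istd(C);
  const double *px = x.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *col = px + j * C;
    for (int c = 0; c < C; ++c) {
      mu[c] += col[c];
      var[c] += col[c] * col[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= (double)M;
    var[c] = var[c] / (double)M - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
    istd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  double *py = y.begin(), *ph = xhat.begin();
  const double *pg = gamma.begin(), *pb = beta.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *col = px + j * C;
    double *yc = py + j * C, *hc = ph + j * C;
    for (int c = 0; c < C; ++c) {
      double h = (col[c] - mu[c]) * istd[c];
      hc[c] = h;
      yc[c] = pg[c] * h + pb[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["istd"] = istd);
}

// Batch-norm backward from cached xhat/istd.
// [[Rcpp::export]]
List cm_bn_bwd(NumericVector g, NumericVector xhat, int C, R_xlen_t M,
               NumericVector gamma, NumericVector istd) {
  NumericVector gx(g.size());
  NumericVector ggamma(C), gbeta(C);
  const double *pg = g.begin(), *ph = xhat.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *gc = pg + j * C, *hc = ph + j * C;
    for (int c = 0; c < C; ++c) {
      ggamma[c] += gc[c] * hc[c];
      gbeta[c] += gc[c];
    }
  }
  NumericVector mg(C), mgh(C);
  for (int c = 0; c < C; ++c) {
    mg[c] = gbeta[c] / (double)M;
    mgh[c] = ggamma[c] / (double)M;
  }
  double *pgx = gx.begin();
  const double *pga = gamma.begin(), *pis = istd.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *gc = pg + j * C, *hc = ph + j * C;
    double *xc = pgx + j * C;
    for (int c = 0; c < C; ++c)
      xc[c] = pga[c] * pis[c] * (gc[c] - mg[c] - hc[c] * mgh[c]);
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// SiLU x * sigmoid(x): forward keeps sigma for the backward pass.
// [[Rcpp::export]]
List cm_silu_fwd(NumericVector x, bool keep) {
  NumericVector y(x.size());
  NumericVector s(keep ? x.size() : 0);
  const double *px = x.begin();
  double *py = y.begin();
  double *ps = keep ? s.begin() : nullptr;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double sg = 1.0 / (1.0 + std::exp(-px[i]));
    py[i] = px[i] * sg;
    if (keep) ps[i] = sg;
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector cm_silu_bwd(NumericVector g, NumericVector x, NumericVector s) {
  NumericVector gx(g.size());
  const double *pg = g.begin(), *px = x.begin(), *ps = s.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i)
    pgx[i] = pg[i] * (ps[i] * (1.0 + px[i] * (1.0 - ps[i])));
  return gx;
}
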