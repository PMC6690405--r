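// Compute kernels for the Dense-U-Net engine and raster post-processing.
// Tensor layout throughout: column-major R arrays dim (H, W, C, N);
// conv kernels dim (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int dim4(const IntegerVector& d, int i) {
  return (i < d.size()) ? d[i] : 1;
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Build the im2col patch matrix for one sample.
// P is (Ho*Wo) x (kh*kw*Cin); column k = i + kh*(j + kw*c).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& P) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int k = i + kh * (j + kw * c);
        double* Pk = P.colptr(k);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) Pk[ho + (size_t)Ho * wo] = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            Pk[ho + (size_t)Ho * wo] = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& P, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int k = i + kh * (j + kw * c);
        const double* Pk = P.colptr(k);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi >= 0 && hi < H) xcw[hi] += Pk[ho + (size_t)Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = dim4(xd, 2), N = dim4(xd, 3);
  int kh = wd[0], kw = wd[1], Ci = wd[2], F = wd[3];
  if (Ci != C) stop("conv: channel mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C;
  NumericVector y = alloc4(Ho, Wo, F, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), F, false, true);
  arma::mat P(Ho * (size_t)Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    arma::mat Y = P * Wm;
    Y.each_row() += bv;
    std::copy(Y.memptr(), Y.memptr() + (size_t)Ho * Wo * F,
              y.begin() + (size_t)Ho * Wo * F * n);
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = dim4(xd, 2), N = dim4(xd, 3);
  int kh = wd[0], kw = wd[1], F = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int K = kh * kw * C;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(kh, kw, C, F);
  NumericVector db(F);
  arma::mat Wm(const_cast<double*>(w.begin()), K, F, false, true);
  arma::mat dWm(dw.begin(), K, F, false, true);
  arma::rowvec dbv(db.begin(), F, false, true);
  arma::mat P(Ho * (size_t)Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, P);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * F * n,
                 Ho * (size_t)Wo, F, false, true);
    dWm += P.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dP = dY * Wm.t();
    col2im_add(dP, H, W, C, kh, kw, stride, pad, Ho, Wo,
               dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Average pooling 2x2 stride 2 (even H, W).
// [[Rcpp::export]]
NumericVector nn_avgpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = dim4(xd, 2), N = dim4(xd, 3);
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  const double* xp = x.begin(); double* yp = y.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + (size_t)H * W * s;
    double* ys = yp + (size_t)Ho * Wo * s;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double* a = xs + (size_t)H * (2 * wo) + 2 * ho;
        const double* bcol = xs + (size_t)H * (2 * wo + 1) + 2 * ho;
        ys[ho + (size_t)Ho * wo] = 0.25 * (a[0] + a[1] + bcol[0] + bcol[1]);
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_avgpool2_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = dim4(yd, 2), N = dim4(yd, 3);
  NumericVector dx = alloc4(H, W, C, N);
  const double* dyp = dy.begin(); double* dxp = dx.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* ds = dyp + (size_t)Ho * Wo * s;
    double* xs = dxp + (size_t)H * W * s;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double g = 0.25 * ds[ho + (size_t)Ho * wo];
        xs[2 * ho     + (size_t)H * (2 * wo)]     += g;
        xs[2 * ho + 1 + (size_t)H * (2 * wo)]     += g;
        xs[2 * ho     + (size_t)H * (2 * wo + 1)] += g;
        xs[2 * ho + 1 + (size_t)H * (2 * wo + 1)] += g;
      }
  }
  return dx;
}

// Max pooling 3x3 stride 2 pad 1 (the DenseNet stem pool); returns argmax for backward.
// [[Rcpp::export]]
List nn_maxpool3s2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = dim4(xd, 2), N = dim4(xd, 3);
  int Ho = (H - 1) / 2 + 1, Wo = (W - 1) / 2 + 1;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + (size_t)H * W * s;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -INFINITY; int bi = 0;
        for (int j = -1; j <= 1; ++j) {
          int wi = 2 * wo + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = -1; i <= 1; ++i) {
            int hi = 2 * ho + i;
            if (hi < 0 || hi >= H) continue;
            double v = xs[hi + (size_t)H * wi];
            if (v > best) { best = v; bi = hi + H * wi; }
          }
        }
        size_t o = ho + (size_t)Ho * wo + (size_t)Ho * Wo * s;
        y[o] = best; idx[o] = bi;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool3s2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = dim4(yd, 2), N = dim4(yd, 3);
  NumericVector dx = alloc4(H, W, C, N);
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    size_t yo = (size_t)Ho * Wo * s, xo = (size_t)H * W * s;
    for (size_t r = 0; r < (size_t)Ho * Wo; ++r)
      dx[xo + idx[yo + r]] += dy[yo + r];
  }
  return dx;
}

// Bilinear x2 upsampling, align_corners = FALSE convention.
static inline void up2_coef(int ho, int H, int& h0, int& h1, double& t) {
  double sh = 0.5 * ho - 0.25;
  if (sh < 0) sh = 0;
  if (sh > H - 1) sh = H - 1;
  h0 = (int)std::floor(sh);
  h1 = std::min(h0 + 1, H - 1);
  t = sh - h0;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = dim4(xd, 2), N = dim4(xd, 3);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = alloc4(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> th(Ho), tw(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, h0[i], h1[i], th[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, w0[j], w1[j], tw[j]);
  const double* xp = x.begin(); double* yp = y.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + (size_t)H * W * s;
    double* ys = yp + (size_t)Ho * Wo * s;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = xs + (size_t)H * w0[j];
      const double* c1 = xs + (size_t)H * w1[j];
      double b = tw[j];
      for (int i = 0; i < Ho; ++i) {
        double a = th[i];
        ys[i + (size_t)Ho * j] =
          (1 - a) * (1 - b) * c0[h0[i]] + a * (1 - b) * c0[h1[i]] +
          (1 - a) * b * c1[h0[i]] + a * b * c1[h1[i]];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = dim4(yd, 2), N = dim4(yd, 3);
  NumericVector dx = alloc4(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> th(Ho), tw(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, h0[i], h1[i], th[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, w0[j], w1[j], tw[j]);
  const double* dyp = dy.begin(); double* dxp = dx.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* ds = dyp + (size_t)Ho * Wo * s;
    double* xs = dxp + (size_t)H * W * s;
    for (int j = 0; j < Wo; ++j) {
      double* c0 = xs + (size_t)H * w0[j];
      double* c1 = xs + (size_t)H * w1[j];
      double b = tw[j];
      for (int i = 0; i < Ho; ++i) {
        double a = th[i], g = ds[i + (size_t)Ho * j];
        c0[h0[i]] += (1 - a) * (1 - b) * g;
        c0[h1[i]] += a * (1 - b) * g;
        c1[h0[i]] += (1 - a) * b * g;
        c1[h1[i]] += a * b * g;
      }
    }
  }
  return dx;
}

// 8-connected component labelling of a binary matrix; labels 1..n in
// first-encounter (column-major scan) order, deterministic.
// [[Rcpp::export]]
IntegerMatrix cc_label8(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w)) continue;
      ++next;
      lab(h, w) = next;
      q.push(h + H * w);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int ph = p % H, pw = p / H;
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            int nh = ph + dh, nw = pw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) && !lab(nh, nw)) {
              lab(nh, nw) = next;
              q.push(nh + H * nw);
            }
          }
      }
    }
  return lab;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of every pixel to the nearest TRUE pixel. Returns squared distances.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_sq(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix D(H, W);
  const double BIG = 1e20;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) f[h] = mask(h, w) ? 0.0 : BIG;
    edt1d(f, d, H);
    for (int h = 0; h < H; ++h) D(h, w) = d[h];
  }
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) f[w] = D(h, w);
    edt1d(f, d, W);
    for (int w = 0; w < W; ++w) D(h, w) = d[w];
  }
  return D;
}

// Constrained label propagation: grow labelled regions into `allowed`
// unlabelled pixels for `iters` rounds of the 3x3 cross. Simultaneous
// update per round = nearest-seed (city-block) assignment; ties take the
// smaller label, deterministically.
// [[Rcpp::export]]
IntegerMatrix propagate_labels(IntegerMatrix lab0, LogicalMatrix allowed, int iters) {
  int H = lab0.nrow(), W = lab0.ncol();
  IntegerMatrix lab = clone(lab0);
  const int dh[4] = {1, -1, 0, 0}, dw[4] = {0, 0, 1, -1};
  for (int it = 0; it < iters; ++it) {
    IntegerMatrix nxt = clone(lab);
    bool changed = false;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        if (lab(h, w) || !allowed(h, w)) continue;
        int best = 0;
        for (int k = 0; k < 4; ++k) {
          int nh = h + dh[k], nw = w + dw[k];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          int l = lab(nh, nw);
          if (l > 0 && (best == 0 || l < best)) best = l;
        }
        if (best) { nxt(h, w) = best; changed = true; }
      }
    lab = nxt;
    if (!changed) break;
  }
  return lab;
}

// Backward warp: out(i,j) = img(map_r(i,j), map_c(i,j)) with 0-based source
// coordinates; interp 0 = nearest, 1 = bilinear; out-of-range -> fill.
// [[Rcpp::export]]
NumericVector warp_image(NumericVector img, NumericMatrix map_r, NumericMatrix map_c,
                         int interp, double fill) {
  IntegerVector xd = img.attr("dim");
  int H = xd[0], W = xd[1], C = (xd.size() > 2) ? xd[2] : 1;
  int Ho = map_r.nrow(), Wo = map_r.ncol();
  NumericVector out(Dimension(Ho, Wo, C));
  const double* xp = img.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    double* oc = out.begin() + (size_t)Ho * Wo * c;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double r = map_r(i, j), cc = map_c(i, j);
        double v;
        if (interp == 0) {
          int ri = (int)std::lround(r), ci = (int)std::lround(cc);
          v = (ri < 0 || ri >= H || ci < 0 || ci >= W) ? fill : xc[ri + (size_t)H * ci];
        } else {
          if (r < 0 || r > H - 1 || cc < 0 || cc > W - 1) {
            v = fill;
          } else {
            int r0 = (int)std::floor(r), c0 = (int)std::floor(cc);
            int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
            double a = r - r0, b = cc - c0;
            v = (1 - a) * (1 - b) * xc[r0 + (size_t)H * c0] +
                a * (1 - b) * xc[r1 + (size_t)H * c0] +
                (1 - a) * b * xc[r0 + (size_t)H * c1] +
                a * b * xc[r1 + (size_t)H * c1];
          }
        }
        oc[i + (size_t)Ho * j] = v;
      }
  }
  return out;
}

// Mean-field inference for a two-label fully-connected CRF with Gaussian
// appearance and smoothness pairwise kernels, truncated at 2.5 sigma.
// img: (H,W,3) in [0,255]; prob: foreground probability matrix.
// [[Rcpp::export]]
NumericMatrix crf_mean_field(NumericVector img, NumericMatrix prob, int iters,
                             double w_app, double sxy_app, double srgb,
                             double w_sm, double sxy_sm) {
  IntegerVector xd = img.attr("dim");
  int H = xd[0], W = xd[1];
  const double* R = img.begin();
  const double* G = R + (size_t)H * W;
  const double* B = G + (size_t)H * W;
  const double eps = 1e-8;
  NumericMatrix Q(H, W);
  NumericMatrix U1(H, W), U0(H, W);  // unary energies: fg, bg
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double p = std::min(1.0 - eps, std::max(eps, prob(i, j)));
      U1(i, j) = -std::log(p);
      U0(i, j) = -std::log(1.0 - p);
      Q(i, j) = p;
    }
  int ra = (int)std::ceil(2.5 * sxy_app), rs = (int)std::ceil(2.5 * sxy_sm);
  // Precompute spatial weights.
  auto spat = [](int r, double s) {
    std::vector<double> w(2 * r + 1);
    for (int d = -r; d <= r; ++d) w[d + r] = std::exp(-0.5 * d * d / (s * s));
    return w;
  };
  std::vector<double> wa = spat(ra, sxy_app), ws = spat(rs, sxy_sm);
  double inv2srgb = 1.0 / (2.0 * srgb * srgb);
  for (int it = 0; it < iters; ++it) {
    NumericMatrix Qn(H, W);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double m1 = 0.0, m0 = 0.0;  // messages: sum k(i,j)*Q_j(fg), *Q_j(bg)
        double r0 = R[i + (size_t)H * j], g0 = G[i + (size_t)H * j], b0 = B[i + (size_t)H * j];
        // appearance kernel
        for (int dj = -ra; dj <= ra; ++dj) {
          int nj = j + dj;
          if (nj < 0 || nj >= W) continue;
          for (int di = -ra; di <= ra; ++di) {
            int ni = i + di;
            if (ni < 0 || ni >= H || (di == 0 && dj == 0)) continue;
            size_t p = ni + (size_t)H * nj;
            double dr = R[p] - r0, dg = G[p] - g0, db = B[p] - b0;
            double k = w_app * wa[di + ra] * wa[dj + ra] *
                       std::exp(-(dr * dr + dg * dg + db * db) * inv2srgb);
            double q = Q(ni, nj);
            m1 += k * q; m0 += k * (1.0 - q);
          }
        }
        // smoothness kernel
        for (int dj = -rs; dj <= rs; ++dj) {
          int nj = j + dj;
          if (nj < 0 || nj >= W) continue;
          for (int di = -rs; di <= rs; ++di) {
            int ni = i + di;
            if (ni < 0 || ni >= H || (di == 0 && dj == 0)) continue;
            double k = w_sm * ws[di + rs] * ws[dj + rs];
            double q = Q(ni, nj);
            m1 += k * q; m0 += k * (1.0 - q);
          }
        }
        // Potts compatibility: penalise disagreement with neighbours.
        double e1 = U1(i, j) + m0;
        double e0 = U0(i, j) + m1;
        double mx = std::max(-e1, -e0);
        double z1 = std::exp(-e1 - mx), z0 = std::exp(-e0 - mx);
        Qn(i, j) = z1 / (z1 + z0);
      }
    Q = Qn;
  }
  return Q;
}
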