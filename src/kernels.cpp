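// Low-level numerical kernels: 2-D convolution forward/backward (im2col + GEMM),
// 2x2 max pooling, and the non-local means filter. Images and feature maps are
// H x W x C arrays (arma::cube with n_rows = H, n_cols = W, n_slices = C).
// Convolution weights are (kh*kw*Cin) x Cout matrices whose row index runs
// i (kernel row) fastest, then j (kernel col), then input channel — i.e. the
// column-major flattening of an R array dim c(kh, kw, Cin).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int pad, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat P(oh * ow, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = c * kh * kw + j * kh + i;
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride + j - pad;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride + i - pad;
            if (iy < 0 || iy >= H) continue;
            P(ox * oh + oy, col) = x(iy, ix, c);
          }
        }
      }
    }
  }
  return P;
}

static arma::cube col2im(const arma::mat& P, int H, int W, int C, int kh,
                         int kw, int stride, int pad, int oh, int ow) {
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = c * kh * kw + j * kh + i;
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride + j - pad;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride + i - pad;
            if (iy < 0 || iy >= H) continue;
            gx(iy, ix, c) += P(ox * oh + oy, col);
          }
        }
      }
    }
  }
  return gx;
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int kh, int kw, int stride, int pad) {
  const int oh = out_size(x.n_rows, kh, stride, pad);
  const int ow = out_size(x.n_cols, kw, stride, pad);
  const int cout = w.n_cols;
  arma::mat P = im2col(x, kh, kw, stride, pad, oh, ow);
  arma::mat O = P * w;           // (oh*ow) x cout
  O.each_row() += b.t();
  arma::cube out(oh, ow, cout);
  std::memcpy(out.memptr(), O.memptr(), sizeof(double) * O.n_elem);
  return out;
}

// Forward pass that keeps the im2col patch matrix alive on the C++ side
// (behind an external pointer) so the backward pass can reuse it without the
// cost of copying it into R.
// [[Rcpp::export]]
List conv2d_fw_cache(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int kh, int kw, int stride, int pad) {
  const int oh = out_size(x.n_rows, kh, stride, pad);
  const int ow = out_size(x.n_cols, kw, stride, pad);
  const int cout = w.n_cols;
  XPtr<arma::mat> Pp(new arma::mat(im2col(x, kh, kw, stride, pad, oh, ow)),
                     true);
  arma::mat O = (*Pp) * w;
  O.each_row() += b.t();
  arma::cube out(oh, ow, cout);
  std::memcpy(out.memptr(), O.memptr(), sizeof(double) * O.n_elem);
  return List::create(Named("out") = out, Named("P") = Pp);
}

// Backward pass reusing the cached patch matrix.
// [[Rcpp::export]]
List conv2d_bw_cache(SEXP Pptr, const arma::mat& w, const arma::cube& gout,
                     int H, int W, int C, int kh, int kw, int stride,
                     int pad) {
  XPtr<arma::mat> P(Pptr);
  const int oh = gout.n_rows, ow = gout.n_cols, cout = gout.n_slices;
  arma::mat G(const_cast<double*>(gout.memptr()), oh * ow, cout, false, true);
  arma::mat gw = P->t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gP = G * w.t();
  arma::cube gx = col2im(gP, H, W, C, kh, kw, stride, pad, oh, ow);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gout,
               int kh, int kw, int stride, int pad) {
  const int oh = gout.n_rows, ow = gout.n_cols, cout = gout.n_slices;
  arma::mat P = im2col(x, kh, kw, stride, pad, oh, ow);
  arma::mat G(const_cast<double*>(gout.memptr()), oh * ow, cout, false, true);
  arma::mat gw = P.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gP = G * w.t();
  arma::cube gx = col2im(gP, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride,
                         pad, oh, ow);
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns the pooled map and
// the 1-based linear index (into the input cube) of each argmax for backprop.
// [[Rcpp::export]]
List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = H / 2, ow = W / 2;
  arma::cube out(oh, ow, C);
  IntegerVector idx(oh * ow * C);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        double best = -arma::datum::inf;
        int besti = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int iy = 2 * oy + di, ix = 2 * ox + dj;
            const double v = x(iy, ix, c);
            if (v > best) {
              best = v;
              besti = c * H * W + ix * H + iy;
            }
          }
        }
        // column-major order of (oy, ox, c) matches p's increment
        out(oy, ox, c) = best;
        idx[p++] = besti + 1;
      }
    }
  }
  return List::create(Named("out") = out, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& gout, const IntegerVector& idx,
                       int H, int W) {
  const int C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const double* g = gout.memptr();
  for (int p = 0; p < (int)idx.size(); ++p) gx(idx[p] - 1) += g[p];
  return gx;
}

// PReLU forward: slope per channel (or a single shared slope).
// [[Rcpp::export]]
arma::cube prelu_fw(const arma::cube& x, const arma::vec& slope) {
  arma::cube out(x.n_rows, x.n_cols, x.n_slices);
  const bool shared = slope.n_elem == 1;
  for (arma::uword c = 0; c < x.n_slices; ++c) {
    const double s = shared ? slope[0] : slope[c];
    const double* xi = x.slice_memptr(c);
    double* oi = out.slice_memptr(c);
    const arma::uword n = x.n_rows * x.n_cols;
    for (arma::uword k = 0; k < n; ++k)
      oi[k] = xi[k] > 0 ? xi[k] : s * xi[k];
  }
  return out;
}

// PReLU backward: gradients for the input and the slope(s).
// [[Rcpp::export]]
List prelu_bw(const arma::cube& x, const arma::vec& slope,
              const arma::cube& gout) {
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices);
  arma::vec gs(slope.n_elem, arma::fill::zeros);
  const bool shared = slope.n_elem == 1;
  for (arma::uword c = 0; c < x.n_slices; ++c) {
    const double s = shared ? slope[0] : slope[c];
    const double* xi = x.slice_memptr(c);
    const double* gi = gout.slice_memptr(c);
    double* oi = gx.slice_memptr(c);
    double acc = 0.0;
    const arma::uword n = x.n_rows * x.n_cols;
    for (arma::uword k = 0; k < n; ++k) {
      if (xi[k] > 0) {
        oi[k] = gi[k];
      } else {
        oi[k] = s * gi[k];
        acc += gi[k] * xi[k];
      }
    }
    gs[shared ? 0 : c] += acc;
  }
  return List::create(Named("gx") = gx, Named("gs") = gs);
}

// Non-local means. For each pixel, a weighted average over the search window
// (clipped at image borders); weight exp(-d2 / h^2) where d2 is the summed
// squared difference of the two patch vectors. Patches are read from an image
// padded by symmetric (mirror) extension of half the patch size.
// [[Rcpp::export]]
arma::mat nlm_filter(const arma::mat& img, int patch, int window, double h) {
  const int H = img.n_rows, W = img.n_cols;
  const int pr = patch / 2, wr = window / 2;
  // mirror-pad
  arma::mat pad(H + 2 * pr, W + 2 * pr);
  for (int j = 0; j < W + 2 * pr; ++j) {
    int sj = j - pr;
    if (sj < 0) sj = -sj - 1;
    if (sj >= W) sj = 2 * W - sj - 1;
    for (int i = 0; i < H + 2 * pr; ++i) {
      int si = i - pr;
      if (si < 0) si = -si - 1;
      if (si >= H) si = 2 * H - si - 1;
      pad(i, j) = img(si, sj);
    }
  }
  const double h2 = h * h;
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int i0 = std::max(0, i - wr), i1 = std::min(H - 1, i + wr);
      const int j0 = std::max(0, j - wr), j1 = std::min(W - 1, j + wr);
      double wsum = 0.0, acc = 0.0;
      for (int l = j0; l <= j1; ++l) {
        for (int k = i0; k <= i1; ++k) {
          double d2 = 0.0;
          for (int v = 0; v < patch; ++v) {
            for (int u = 0; u < patch; ++u) {
              const double d = pad(i + u, j + v) - pad(k + u, l + v);
              d2 += d * d;
            }
          }
          const double wgt = std::exp(-d2 / h2);
          wsum += wgt;
          acc += wgt * img(k, l);
        }
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
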