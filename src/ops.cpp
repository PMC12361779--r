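// Low-level tensor primitives for the network core.
//
// Batched feature maps are stored as column-major R matrices of shape
// (N*H*W, C): column c holds channel c for all images, rows ordered
// image-major, then image row y, then image column x. This keeps each
// channel contiguous (good for depthwise loops) and turns every 1x1
// convolution into a single BLAS GEMM on the R side.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Unfold k x k patches: (N*H*W, C) -> (N*Ho*Wo, C*k*k).
// Output column index j = (c*k + ky)*k + kx; weight matrices for dense
// convolutions must use the same row ordering.
// [[Rcpp::export]]
NumericMatrix nn_im2col(const NumericMatrix& x, int n, int h, int w,
                        int k, int stride, int pad) {
  const int C = x.ncol();
  const int ho = out_dim(h, k, stride, pad);
  const int wo = out_dim(w, k, stride, pad);
  NumericMatrix out((R_xlen_t)n * ho * wo, C * k * k);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        double* oc = &out(0, (c * k + ky) * k + kx);
        for (int ni = 0; ni < n; ++ni) {
          for (int oy = 0; oy < ho; ++oy) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= h) continue;
            const R_xlen_t orow = ((R_xlen_t)ni * ho + oy) * wo;
            const R_xlen_t irow = ((R_xlen_t)ni * h + iy) * w;
            for (int ox = 0; ox < wo; ++ox) {
              const int ix = ox * stride + kx - pad;
              if (ix < 0 || ix >= w) continue;
              oc[orow + ox] = xc[irow + ix];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of nn_im2col: scatter-add patch gradients back to the input.
// [[Rcpp::export]]
NumericMatrix nn_col2im(const NumericMatrix& dcol, int n, int h, int w,
                        int C, int k, int stride, int pad) {
  const int ho = out_dim(h, k, stride, pad);
  const int wo = out_dim(w, k, stride, pad);
  NumericMatrix dx((R_xlen_t)n * h * w, C);
  for (int c = 0; c < C; ++c) {
    double* xc = &dx(0, c);
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        const double* oc = &dcol(0, (c * k + ky) * k + kx);
        for (int ni = 0; ni < n; ++ni) {
          for (int oy = 0; oy < ho; ++oy) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= h) continue;
            const R_xlen_t orow = ((R_xlen_t)ni * ho + oy) * wo;
            const R_xlen_t irow = ((R_xlen_t)ni * h + iy) * w;
            for (int ox = 0; ox < wo; ++ox) {
              const int ix = ox * stride + kx - pad;
              if (ix < 0 || ix >= w) continue;
              xc[irow + ix] += oc[orow + ox];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise convolution forward. wgt has shape (k*k, C), row (ky*k + kx).
// The interior (no padding clipping) runs unchecked; borders fall back to
// a clipped loop.
static void dw_fwd_plane(const double* __restrict__ xim, const double* __restrict__ wc, double* __restrict__ yim,
                         int h, int w, int ho, int wo, int k, int stride,
                         int pad) {
  int xlo = (pad + stride - 1) / stride;
  int xhi = (w - k + pad) / stride;            // inclusive
  if (xhi > wo - 1) xhi = wo - 1;
  if (xlo > wo) xlo = wo;
  for (int oy = 0; oy < ho; ++oy) {
    const int iy0 = oy * stride - pad;
    double* yr = yim + (R_xlen_t)oy * wo;
    const bool row_ok = iy0 >= 0 && iy0 + k <= h;
    if (row_ok && xhi >= xlo) {
      // interior: accumulate kernel taps over contiguous input rows
      for (int ox = xlo; ox <= xhi; ++ox) yr[ox] = 0.0;
      for (int ky = 0; ky < k; ++ky) {
        const double* xr = xim + (R_xlen_t)(iy0 + ky) * w - pad;
        for (int kx = 0; kx < k; ++kx) {
          const double wv = wc[ky * k + kx];
          const double* xp = xr + kx + (R_xlen_t)xlo * stride;
          if (stride == 1) {
            for (int ox = xlo; ox <= xhi; ++ox) yr[ox] += wv * xp[ox - xlo];
          } else {
            for (int ox = xlo; ox <= xhi; ++ox)
              yr[ox] += wv * xp[(R_xlen_t)(ox - xlo) * stride];
          }
        }
      }
    }
    // clipped borders (and whole row when clipped vertically)
    for (int ox = 0; ox < wo; ++ox) {
      if (row_ok && ox >= xlo && ox <= xhi) continue;
      double acc = 0.0;
      for (int ky = 0; ky < k; ++ky) {
        const int iy = iy0 + ky;
        if (iy < 0 || iy >= h) continue;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= w) continue;
          acc += wc[ky * k + kx] * xim[(R_xlen_t)iy * w + ix];
        }
      }
      yr[ox] = acc;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix nn_dwconv_fwd(const NumericMatrix& x, const NumericMatrix& wgt,
                            int n, int h, int w, int k, int stride, int pad) {
  const int C = x.ncol();
  const int ho = out_dim(h, k, stride, pad);
  const int wo = out_dim(w, k, stride, pad);
  NumericMatrix y((R_xlen_t)n * ho * wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* wc = &wgt(0, c);
    double* yc = &y(0, c);
    for (int ni = 0; ni < n; ++ni)
      dw_fwd_plane(xc + (R_xlen_t)ni * h * w, wc,
                   yc + (R_xlen_t)ni * ho * wo, h, w, ho, wo, k, stride, pad);
  }
  return y;
}

// Depthwise convolution: gradient w.r.t. the input. At stride 1 this is
// the same-padded correlation with the flipped kernel, so the fast
// forward path is reused; stride 2 uses a scatter loop.
// [[Rcpp::export]]
NumericMatrix nn_dwconv_bwd_x(const NumericMatrix& dy, const NumericMatrix& wgt,
                              int n, int h, int w, int k, int stride, int pad) {
  const int C = dy.ncol();
  const int ho = out_dim(h, k, stride, pad);
  const int wo = out_dim(w, k, stride, pad);
  NumericMatrix dx((R_xlen_t)n * h * w, C);
  if (stride == 1) {
    std::vector<double> wf(k * k);
    for (int c = 0; c < C; ++c) {
      const double* wc = &wgt(0, c);
      for (int i = 0; i < k * k; ++i) wf[i] = wc[k * k - 1 - i];
      const double* gc = &dy(0, c);
      double* xc = &dx(0, c);
      for (int ni = 0; ni < n; ++ni)
        dw_fwd_plane(gc + (R_xlen_t)ni * ho * wo, wf.data(),
                     xc + (R_xlen_t)ni * h * w, ho, wo, h, w, k, 1,
                     k - 1 - pad);
    }
    return dx;
  }
  for (int c = 0; c < C; ++c) {
    const double* gc = &dy(0, c);
    const double* wc = &wgt(0, c);
    double* xc = &dx(0, c);
    for (int ni = 0; ni < n; ++ni) {
      for (int oy = 0; oy < ho; ++oy) {
        const R_xlen_t orow = ((R_xlen_t)ni * ho + oy) * wo;
        for (int ox = 0; ox < wo; ++ox) {
          const double g = gc[orow + ox];
          if (g == 0.0) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= h) continue;
            const R_xlen_t irow = ((R_xlen_t)ni * h + iy) * w;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride + kx - pad;
              if (ix < 0 || ix >= w) continue;
              xc[irow + ix] += g * wc[ky * k + kx];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise convolution: gradient w.r.t. the kernel, shape (k*k, C).
// [[Rcpp::export]]
NumericMatrix nn_dwconv_bwd_w(const NumericMatrix& x, const NumericMatrix& dy,
                              int n, int h, int w, int k, int stride, int pad) {
  const int C = x.ncol();
  const int ho = out_dim(h, k, stride, pad);
  const int wo = out_dim(w, k, stride, pad);
  NumericMatrix dw(k * k, C);
  int xlo = (pad + stride - 1) / stride;
  int xhi = (w - k + pad) / stride;
  if (xhi > wo - 1) xhi = wo - 1;
  if (xlo > wo) xlo = wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    const double* gc = &dy(0, c);
    double* wc = &dw(0, c);
    for (int ni = 0; ni < n; ++ni) {
      const double* xim = xc + (R_xlen_t)ni * h * w;
      const double* gim = gc + (R_xlen_t)ni * ho * wo;
      for (int oy = 0; oy < ho; ++oy) {
        const int iy0 = oy * stride - pad;
        const bool row_ok = iy0 >= 0 && iy0 + k <= h;
        const double* gr = gim + (R_xlen_t)oy * wo;
        if (row_ok && xhi >= xlo) {
          for (int ky = 0; ky < k; ++ky) {
            const double* xr = xim + (R_xlen_t)(iy0 + ky) * w - pad;
            for (int kx = 0; kx < k; ++kx) {
              const double* xp = xr + kx + (R_xlen_t)xlo * stride;
              double acc = 0.0;
              if (stride == 1) {
                for (int ox = xlo; ox <= xhi; ++ox)
                  acc += gr[ox] * xp[ox - xlo];
              } else {
                for (int ox = xlo; ox <= xhi; ++ox)
                  acc += gr[ox] * xp[(R_xlen_t)(ox - xlo) * stride];
              }
              wc[ky * k + kx] += acc;
            }
          }
        }
        for (int ox = 0; ox < wo; ++ox) {
          if (row_ok && ox >= xlo && ox <= xhi) continue;
          const double g = gr[ox];
          if (g == 0.0) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= h) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride + kx - pad;
              if (ix < 0 || ix >= w) continue;
              wc[ky * k + kx] += g * xim[(R_xlen_t)iy * w + ix];
            }
          }
        }
      }
    }
  }
  return dw;
}

static inline double edge_sample(const double* ch, int h, int w,
                                 double sy, double sx) {
  // Bilinear sample with nearest-edge extension (column-major H x W plane).
  if (sy < 0) sy = 0; if (sy > h - 1) sy = h - 1;
  if (sx < 0) sx = 0; if (sx > w - 1) sx = w - 1;
  const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
  const int y1 = std::min(y0 + 1, h - 1), x1 = std::min(x0 + 1, w - 1);
  const double fy = sy - y0, fx = sx - x0;
  const double v00 = ch[y0 + (R_xlen_t)x0 * h], v01 = ch[y0 + (R_xlen_t)x1 * h];
  const double v10 = ch[y1 + (R_xlen_t)x0 * h], v11 = ch[y1 + (R_xlen_t)x1 * h];
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Inverse-map affine warp of an H x W x C array. A is the 2x2 output->input
// linear map about the image centre, t the additional input-space offset
// (pixels). Out-of-frame samples take the nearest edge value.
// [[Rcpp::export]]
NumericVector nn_affine_warp(const NumericVector& img, int h, int w, int C,
                             const NumericMatrix& A, const NumericVector& t) {
  NumericVector out((R_xlen_t)h * w * C);
  out.attr("dim") = IntegerVector::create(h, w, C);
  const double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  for (int c = 0; c < C; ++c) {
    const double* ch = &img[(R_xlen_t)c * h * w];
    double* oc = &out[(R_xlen_t)c * h * w];
    for (int x = 0; x < w; ++x) {
      const double dx = x - cx;
      for (int y = 0; y < h; ++y) {
        const double dy = y - cy;
        const double sy = A(0, 0) * dy + A(0, 1) * dx + cy + t[0];
        const double sx = A(1, 0) * dy + A(1, 1) * dx + cx + t[1];
        oc[y + (R_xlen_t)x * h] = edge_sample(ch, h, w, sy, sx);
      }
    }
  }
  return out;
}

// Bilinear resize of an H x W x C array (align-corners-false convention).
// [[Rcpp::export]]
NumericVector nn_resize_bilinear(const NumericVector& img, int h, int w, int C,
                                 int oh, int ow) {
  NumericVector out((R_xlen_t)oh * ow * C);
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  const double ry = (double)h / oh, rx = (double)w / ow;
  for (int c = 0; c < C; ++c) {
    const double* ch = &img[(R_xlen_t)c * h * w];
    double* oc = &out[(R_xlen_t)c * oh * ow];
    for (int x = 0; x < ow; ++x) {
      const double sx = (x + 0.5) * rx - 0.5;
      for (int y = 0; y < oh; ++y) {
        const double sy = (y + 0.5) * ry - 0.5;
        oc[y + (R_xlen_t)x * oh] = edge_sample(ch, h, w, sy, sx);
      }
    }
  }
  return out;
}
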