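// Numerical kernels for the segmentation network and preprocessing.
// Feature maps are arma::cube with layout (H rows, W cols, C slices),
// matching R arrays of dim c(H, W, C).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Gather "same"-padded, dilated kernel neighbourhoods into an
// (H*W) x (kh*kw*C) matrix (pixels as rows, so every in-bounds run over r
// is a contiguous copy). Zero padding; tap (i,j,c) has column index
// i + kh*(j + kw*c), matching an R weight array of dim (kh, kw, Cin, Cout)
// flattened column-major.
static mat im2col_dil(const cube& x, int kh, int kw, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  mat cols(H * W, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * (j + kw * c);
        const int dr = (i - ch) * dil, dc = (j - cw) * dil;
        const int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        if (r1 < r0) continue;
        const int len = r1 - r0 + 1;
        const int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
        double* dst_base = cols.colptr(q);
        for (int cc = c0; cc <= c1; ++cc)
          std::memcpy(dst_base + r0 + H * cc,
                      &x(r0 + dr, cc + dc, c), len * sizeof(double));
      }
  return cols;
}

// Cross-correlation with dilation, "same" zero padding, linear output.
// w: (kh*kw*Cin) x Cout, b: length Cout.
// [[Rcpp::export]]
arma::cube conv2d_fw_cpp(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int kh, int kw, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  mat y = im2col_dil(x, kh, kw, dil) * w;  // (H*W) x Cout
  y.each_row() += b.t();
  const int Cout = w.n_cols;
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(),
              (size_t)H * W * Cout * sizeof(double));
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw_cpp(const arma::cube& x, const arma::mat& w,
                         const arma::cube& dy, int kh, int kw, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  mat dymat(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  mat cols = im2col_dil(x, kh, kw, dil);
  mat dw = cols.t() * dymat;               // (kh*kw*C) x Cout
  vec db = sum(dymat, 0).t();
  mat dcols = dymat * w.t();               // (H*W) x (kh*kw*C)
  cube dx(H, W, C, fill::zeros);
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * (j + kw * c);
        const int dr = (i - ch) * dil, dc = (j - cw) * dil;
        const int r0 = std::max(0, -dr), r1 = std::min(H - 1, H - 1 - dr);
        if (r1 < r0) continue;
        const int len = r1 - r0 + 1;
        const int c0 = std::max(0, -dc), c1 = std::min(W - 1, W - 1 - dc);
        const double* src_base = dcols.colptr(q);
        for (int cc = c0; cc <= c1; ++cc) {
          const double* src = src_base + r0 + H * cc;
          double* dst = &dx(r0 + dr, cc + dc, c);
          for (int r = 0; r < len; ++r) dst[r] += src[r];
        }
      }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; H and W must be even (caller pads).
// Returns pooled map and flat argmax index (r + H*c, 0-based) per window.
// [[Rcpp::export]]
Rcpp::List maxpool2_fw_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  icube arg(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int wc = 0; wc < Wo; ++wc)
      for (int r = 0; r < Ho; ++r) {
        double best = -datum::inf; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int sr = 2 * r + di, sc = 2 * wc + dj;
            const double v = x(sr, sc, c);
            if (v > best) { best = v; bi = sr + H * sc; }
          }
        out(r, wc, c) = best;
        arg(r, wc, c) = bi;
      }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw_cpp(const arma::cube& dy, const arma::icube& arg,
                           int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int wc = 0; wc < Wo; ++wc)
      for (int r = 0; r < Ho; ++r) {
        const int flat = arg(r, wc, c);
        dx(flat % H, flat / H, c) += dy(r, wc, c);
      }
  return dx;
}

// Bilinear resize with half-pixel centre alignment:
// src = (i + 0.5) * in/out - 0.5, clamped to the valid range.
static void bilin_coeffs(int n_in, int n_out, ivec& i0, ivec& i1, vec& t) {
  i0.set_size(n_out); i1.set_size(n_out); t.set_size(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int lo = (int)std::floor(s);
    if (lo > n_in - 2) lo = n_in - 2;
    if (lo < 0) lo = 0;
    i0[i] = lo; i1[i] = (n_in == 1) ? lo : lo + 1;
    t[i] = s - lo;
  }
}

// [[Rcpp::export]]
arma::cube bilin_resize_cpp(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  ivec r0, r1, c0, c1; vec tr, tc;
  bilin_coeffs(H, oh, r0, r1, tr);
  bilin_coeffs(W, ow, c0, c1, tc);
  cube out(oh, ow, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double a = x(r0[i], c0[j], c), b = x(r0[i], c1[j], c);
        const double d = x(r1[i], c0[j], c), e = x(r1[i], c1[j], c);
        const double top = a + tc[j] * (b - a);
        const double bot = d + tc[j] * (e - d);
        out(i, j, c) = top + tr[i] * (bot - top);
      }
  return out;
}

// Adjoint (transpose) of bilin_resize_cpp, for backprop through upsampling.
// [[Rcpp::export]]
arma::cube bilin_resize_adj_cpp(const arma::cube& dy, int ih, int iw) {
  const int oh = dy.n_rows, ow = dy.n_cols, C = dy.n_slices;
  ivec r0, r1, c0, c1; vec tr, tc;
  bilin_coeffs(ih, oh, r0, r1, tr);
  bilin_coeffs(iw, ow, c0, c1, tc);
  cube dx(ih, iw, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double g = dy(i, j, c);
        const double wr1 = tr[i], wr0 = 1.0 - wr1;
        const double wc1 = tc[j], wc0 = 1.0 - wc1;
        dx(r0[i], c0[j], c) += g * wr0 * wc0;
        dx(r0[i], c1[j], c) += g * wr0 * wc1;
        dx(r1[i], c0[j], c) += g * wr1 * wc0;
        dx(r1[i], c1[j], c) += g * wr1 * wc1;
      }
  return dx;
}

// Inverse-map affine resampling for the co-transforms:
// out(r, c) = img(a11*r + a12*c + b1, a21*r + a22*c + b2), 0-based coords,
// bilinear or nearest (round-half-away-from-zero), fill outside the frame.
// [[Rcpp::export]]
arma::mat affine_sample_cpp(const arma::mat& img, double a11, double a12,
                            double a21, double a22, double b1, double b2,
                            bool bilinear, double fill) {
  const int H = img.n_rows, W = img.n_cols;
  mat out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const double sr = a11 * r + a12 * c + b1;
      const double sc = a21 * r + a22 * c + b2;
      if (bilinear) {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        if (r0 < -1 || r0 > H - 1 || c0 < -1 || c0 > W - 1) {
          out(r, c) = fill; continue;
        }
        const double tr = sr - r0, tc = sc - c0;
        auto at = [&](int rr, int cc) {
          return (rr < 0 || rr >= H || cc < 0 || cc >= W) ? fill : img(rr, cc);
        };
        const double top = at(r0, c0) + tc * (at(r0, c0 + 1) - at(r0, c0));
        const double bot = at(r0 + 1, c0) + tc * (at(r0 + 1, c0 + 1) - at(r0 + 1, c0));
        out(r, c) = top + tr * (bot - top);
      } else {
        const long ri = std::lround(sr), ci = std::lround(sc);
        out(r, c) = (ri < 0 || ri >= H || ci < 0 || ci >= W) ? fill : img(ri, ci);
      }
    }
  return out;
}

// Non-local means on a 2D image. Patch distances use replicate padding
// (indices clamped to the frame); weights exp(-SSD/h^2) include the centre
// patch itself and are normalised per pixel.
// [[Rcpp::export]]
arma::mat nlmeans_cpp(const arma::mat& img, int patch, int window, double h) {
  const int H = img.n_rows, W = img.n_cols;
  const int pr = (patch - 1) / 2, wr = (window - 1) / 2;
  const double h2 = h * h;
  auto at = [&](int r, int c) {
    if (r < 0) r = 0; if (r >= H) r = H - 1;
    if (c < 0) c = 0; if (c >= W) c = W - 1;
    return img(r, c);
  };
  mat out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double wsum = 0.0, vsum = 0.0;
      for (int qc = c - wr; qc <= c + wr; ++qc)
        for (int qr = r - wr; qr <= r + wr; ++qr) {
          double d2 = 0.0;
          for (int oc = -pr; oc <= pr; ++oc)
            for (int orr = -pr; orr <= pr; ++orr) {
              const double diff = at(r + orr, c + oc) - at(qr + orr, qc + oc);
              d2 += diff * diff;
            }
          const double wgt = std::exp(-d2 / h2);
          wsum += wgt;
          vsum += wgt * at(qr, qc);
        }
      out(r, c) = vsum / wsum;
    }
  return out;
}
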