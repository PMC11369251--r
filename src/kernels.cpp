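// Convolution / pooling kernels backing the autodiff engine.
// Layout convention: feature maps are arma::cube (H, W, C) mapping directly
// onto R arrays dim = c(H, W, C); conv weights are R arrays
// dim = c(kh, kw, Cin, Cout), flattened column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col: rows index output pixels (row-fastest), columns index
// (ki, kj, c) with ki fastest — matches column-major weight flattening.
static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(Ho * (long)Wo, (long)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const long ccol = ki + (long)kh * (kj + (long)kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            col(oi + (long)Ho * oj, ccol) = x(i, j, c);
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(arma::cube& gx, const arma::mat& gcol, int kh, int kw,
                       int stride, int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const long ccol = ki + (long)kh * (kj + (long)kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            gx(i, j, c) += gcol(oi + (long)Ho * oj, ccol);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const NumericVector& w,
                      const arma::vec& b, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if ((int)x.n_slices != Cin) stop("conv2d: channel mismatch");
  const int Ho = (x.n_rows + 2 * pad - kh) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), (long)kh * kw * Cin, Cout, false);
  arma::mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat y = col * Wm;
  y.each_row() += b.t();
  return arma::cube(y.memptr(), Ho, Wo, Cout);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const NumericVector& w,
                   const arma::cube& gy, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::mat Wm(const_cast<double*>(w.begin()), (long)kh * kw * Cin, Cout, false);
  arma::mat gym(const_cast<double*>(gy.memptr()), (long)Ho * Wo, Cout, false);
  arma::mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat gw = col.t() * gym;            // (kh*kw*Cin) x Cout
  arma::vec gb = arma::sum(gym, 0).t();
  arma::mat gcol = gym * Wm.t();
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  col2im_add(gx, gcol, kh, kw, stride, pad, Ho, Wo);
  NumericVector gwv(gw.memptr(), gw.memptr() + gw.n_elem);
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled map and linear (1-based)
// argmax indices into the input cube for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * (long)Wo * C);
  long p = 0;
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < Wo; ++oj)
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -std::numeric_limits<double>::infinity();
        long bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * oi + di, j = 2 * oj + dj;
            const double v = x(i, j, c);
            if (v > best) { best = v; bidx = i + (long)H * j + (long)H * W * c; }
          }
        y(oi, oj, c) = best;
        idx[p++] = (int)(bidx + 1);
      }
  IntegerVector dim = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = dim;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// 8-connected component labeling of a binary mask by flood fill.
// Returns an integer matrix of labels (0 = background, 1..K components).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<long> stack;
  int next = 0;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (mask(i0, j0) == 0 || lab(i0, j0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i0 + (long)H * j0);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        const long p = stack.back(); stack.pop_back();
        const int i = p % H, j = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = i + di, nj = j + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + (long)H * nj);
            }
          }
      }
    }
  return lab;
}
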