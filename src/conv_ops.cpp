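// Minimal convolutional kernels for the attention U-Net: same-padded 3x3
// (or any odd k) convolutions via im2col + GEMM, with hand-written
// backward passes, plus 2x2 max pooling. Tensors are arma::cube [H, W, C].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column matrix [H*W, k*k*C] of zero-padded k x k neighbourhoods
static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = k / 2;
  mat cols(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dj = -half; dj <= half; ++dj) {
      for (int di = -half; di <= half; ++di) {
        const int col_idx = c * k * k + (dj + half) * k + (di + half);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc.colptr(j + dj) + (i0 + di);
          double* dst = cols.colptr(col_idx) + (j * H + i0);
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return cols;
}

// scatter-add of column gradients back into the padded input
static cube col2im_same(const mat& cols, const int H, const int W,
                        const int C, const int k) {
  const int half = k / 2;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    for (int dj = -half; dj <= half; ++dj) {
      for (int di = -half; di <= half; ++di) {
        const int col_idx = c * k * k + (dj + half) * k + (di + half);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = cols.colptr(col_idx) + (j * H + i0);
          double* dst = gc.colptr(j + dj) + (i0 + di);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return gx;
}

// y[h,w,co] = sum_{ci,di,dj} x[h+di, w+dj, ci] * wgt[(ci,di,dj), co] + b[co]
// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& wgt,
                       const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = wgt.n_cols;
  mat cols = im2col_same(x, k);
  mat y = cols * wgt;
  y.each_row() += b.t();
  cube out(H, W, Cout);
  std::copy(y.memptr(), y.memptr() + y.n_elem, out.memptr());
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::mat& wgt,
                       const arma::cube& gy, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  mat gymat(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  mat cols = im2col_same(x, k);
  mat gw = cols.t() * gymat;
  vec gb = sum(gymat, 0).t();
  mat gcols = gymat * wgt.t();
  cube gx = col2im_same(gcols, H, W, C, k);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling; returns pooled cube and 1-based argmax linear indices
// [[Rcpp::export]]
Rcpp::List nn_maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bi = (uword)c * H * W + (uword)jj * H + ii;
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi + 1;  // 1-based for R
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube nn_maxpool_bwd(const arma::cube& gy, const arma::ucube& idx,
                          const int H, const int W, const int C) {
  cube gx(H, W, C, fill::zeros);
  const uword n = gy.n_elem;
  const double* g = gy.memptr();
  const uword* id = idx.memptr();
  double* out = gx.memptr();
  for (uword t = 0; t < n; ++t) out[id[t] - 1] += g[t];
  return gx;
}
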