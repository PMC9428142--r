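#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Image tensors are R arrays with dim (H, W, C), column-major:
// element (i, j, c) lives at i + H*j + H*W*c (all 0-based here).
// im2col column ordering: output location index L = oi + Ho*oj (row fastest),
// row ordering within a column: r = ki + kh*(kj + kw*c).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  const int L = Ho * Wo;
  NumericMatrix cols(K, L);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const int l = oi + Ho * oj;
      double *col = pc + (R_xlen_t)l * K;
      const int i0 = oi * stride - pad;
      const int j0 = oj * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double *plane = px + (R_xlen_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int j = j0 + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int i = i0 + ki;
            const int r = ki + kh * (kj + kw * c);
            col[r] = (i >= 0 && i < H && j >= 0 && j < W)
                       ? plane[i + (R_xlen_t)H * j] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add of patch columns back into an (H, W, C) array; adjoint of
// im2col_cpp, also used as overlap-add forward of the transposed convolution.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out((R_xlen_t)H * W * C);
  double *po = out.begin();
  const double *pc = cols.begin();
  const int K = kh * kw * C;
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const int l = oi + Ho * oj;
      const double *col = pc + (R_xlen_t)l * K;
      const int i0 = oi * stride - pad;
      const int j0 = oj * stride - pad;
      for (int c = 0; c < C; ++c) {
        double *plane = po + (R_xlen_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int i = i0 + ki;
            if (i < 0 || i >= H) continue;
            plane[i + (R_xlen_t)H * j] += col[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// indices into the input array (for the backward scatter).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t xoff = (R_xlen_t)c * H * W;
    const R_xlen_t yoff = (R_xlen_t)c * Ho * Wo;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = R_NegInf;
        R_xlen_t besti = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const R_xlen_t k = xoff + (2 * oi + di) + (R_xlen_t)H * (2 * oj + dj);
            if (px[k] > best) { best = px[k]; besti = k; }
          }
        }
        y[yoff + oi + (R_xlen_t)Ho * oj] = best;
        idx[yoff + oi + (R_xlen_t)Ho * oj] = (int)(besti + 1);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               int H, int W, int C) {
  NumericVector dx((R_xlen_t)H * W * C);
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[idx[k] - 1] += dy[k];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Connected-component labelling of a binary matrix, 8-connectivity (BFS).
// Returns an integer matrix of labels 0 (background), 1..n.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
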