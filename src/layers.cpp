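// Compiled kernels: connected-component labeling and the layer primitives
// (3x3 same-padding convolution, 2x2 max-pool, nearest 2x upsample) used by
// the compact U-Net backend. All cubes are (H, W, C), column-major.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Label connected foreground components of a binary mask.
// connectivity: 4 or 8. Labels are renumbered so that components are ordered
// by (min row, min col) over their pixel sets; ties broken by scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> minr, minc, order;
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  for (int r = 0; r < H; ++r) {    // row-major scan: first pixel found has min row
    for (int c = 0; c < W; ++c) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        int mr = r, mc = c;
        std::queue<std::pair<int, int> > q;
        lab(r, c) = next;
        q.push(std::make_pair(r, c));
        while (!q.empty()) {
          std::pair<int, int> p = q.front(); q.pop();
          if (p.first < mr) mr = p.first;
          if (p.second < mc) mc = p.second;
          for (int k = 0; k < nn; ++k) {
            int rr = p.first + dr[k], cc = p.second + dc[k];
            if (rr >= 0 && rr < H && cc >= 0 && cc < W &&
                mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
        minr.push_back(mr);
        minc.push_back(mc);
      }
    }
  }
  // renumber by (min row, min col), stable in discovery order
  std::vector<int> idx(next);
  for (int i = 0; i < next; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (minr[a] != minr[b]) return minr[a] < minr[b];
    return minc[a] < minc[b];
  });
  std::vector<int> remap(next + 1, 0);
  for (int i = 0; i < next; ++i) remap[idx[i] + 1] = i + 1;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (lab(r, c) != 0) lab(r, c) = remap[lab(r, c)];
  return lab;
}

// im2col for 3x3 kernels with zero same-padding.
// Output: (H*W) x (Cin*9); column ci*9 + ky*3 + kx holds input slice ci
// shifted by (ky-1, kx-1).
static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, C * 9, arma::fill::zeros);
  for (arma::uword ci = 0; ci < C; ++ci) {
    const arma::mat& s = x.slice(ci);
    for (int ky = 0; ky < 3; ++ky) {
      for (int kx = 0; kx < 3; ++kx) {
        const int oy = ky - 1, ox = kx - 1;   // source offset
        arma::uword col = ci * 9 + ky * 3 + kx;
        // destination pixel (r, c) reads source (r + oy, c + ox)
        arma::uword r0 = (oy < 0) ? 1 : 0, r1 = (oy > 0) ? H - 1 : H;
        arma::uword c0 = (ox < 0) ? 1 : 0, c1 = (ox > 0) ? W - 1 : W;
        for (arma::uword c = c0; c < c1; ++c) {
          double* dst = out.colptr(col) + c * H;
          const double* src = s.colptr(c + ox) + r0 + oy;
          std::copy(src, src + (r1 - r0), dst + r0);
        }
      }
    }
  }
  return out;
}

// Scatter-add the im2col layout back onto an input-shaped cube.
static arma::cube col2im3(const arma::mat& cols, arma::uword H, arma::uword W,
                          arma::uword C) {
  arma::cube out(H, W, C, arma::fill::zeros);
  for (arma::uword ci = 0; ci < C; ++ci) {
    arma::mat& s = out.slice(ci);
    for (int ky = 0; ky < 3; ++ky) {
      for (int kx = 0; kx < 3; ++kx) {
        const int oy = ky - 1, ox = kx - 1;
        arma::uword col = ci * 9 + ky * 3 + kx;
        arma::uword r0 = (oy < 0) ? 1 : 0, r1 = (oy > 0) ? H - 1 : H;
        arma::uword c0 = (ox < 0) ? 1 : 0, c1 = (ox > 0) ? W - 1 : W;
        for (arma::uword c = c0; c < c1; ++c) {
          double* dst = s.colptr(c + ox) + r0 + oy;
          const double* src = cols.colptr(col) + c * H + r0;
          for (arma::uword r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return out;
}

// y = conv3x3(x, W) + b. Wm: (Cin*9) x Cout, b: length Cout.
// [[Rcpp::export]]
arma::cube cpp_conv3x3_fwd(const arma::cube& x, const arma::mat& Wm,
                           const arma::rowvec& b) {
  const arma::uword H = x.n_rows, W = x.n_cols, Cout = Wm.n_cols;
  arma::mat Y = im2col3(x) * Wm;       // (H*W) x Cout
  Y.each_row() += b;
  arma::cube out(H, W, Cout);
  for (arma::uword co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(Y.col(co), H, W);
  return out;
}

// Gradients of conv3x3 w.r.t. input, weights and bias.
// [[Rcpp::export]]
List cpp_conv3x3_bwd(const arma::cube& x, const arma::mat& Wm,
                     const arma::cube& dy) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  const arma::uword Cin = x.n_slices, Cout = dy.n_slices;
  arma::mat dYm(H * W, Cout);
  for (arma::uword co = 0; co < Cout; ++co)
    dYm.col(co) = arma::vectorise(dy.slice(co));
  arma::mat X = im2col3(x);
  arma::mat dW = X.t() * dYm;                        // (Cin*9) x Cout
  arma::rowvec db = arma::sum(dYm, 0);
  arma::cube dx = col2im3(dYm * Wm.t(), H, W, Cin);
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// 2x2 max-pool, stride 2. Even H and W required (enforced by the R caller).
// Returns pooled cube and per-slice linear argmax indices for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::umat idx(h * w, C);
  for (arma::uword ci = 0; ci < C; ++ci) {
    const arma::mat& s = x.slice(ci);
    for (arma::uword cc = 0; cc < w; ++cc) {
      for (arma::uword rr = 0; rr < h; ++rr) {
        arma::uword best = 2 * rr + 2 * cc * H;
        double bv = s(2 * rr, 2 * cc);
        const arma::uword cand[3] = {2 * rr + 1 + 2 * cc * H,
                                     2 * rr + (2 * cc + 1) * H,
                                     2 * rr + 1 + (2 * cc + 1) * H};
        for (int k = 0; k < 3; ++k)
          if (s(cand[k]) > bv) { bv = s(cand[k]); best = cand[k]; }
        y(rr, cc, ci) = bv;
        idx(rr + cc * h, ci) = best;
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::umat& idx,
                            int H, int W) {
  const arma::uword C = dy.n_slices, h = dy.n_rows, w = dy.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword ci = 0; ci < C; ++ci) {
    arma::mat& s = dx.slice(ci);
    const arma::mat& d = dy.slice(ci);
    for (arma::uword j = 0; j < h * w; ++j) s(idx(j, ci)) += d(j);
  }
  return dx;
}

// Nearest-neighbour 2x upsample.
// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (arma::uword ci = 0; ci < C; ++ci) {
    const arma::mat& s = x.slice(ci);
    arma::mat& o = y.slice(ci);
    for (arma::uword cc = 0; cc < W; ++cc)
      for (arma::uword rr = 0; rr < H; ++rr) {
        const double v = s(rr, cc);
        o(2 * rr, 2 * cc) = v; o(2 * rr + 1, 2 * cc) = v;
        o(2 * rr, 2 * cc + 1) = v; o(2 * rr + 1, 2 * cc + 1) = v;
      }
  }
  return y;
}

// Backward of nearest 2x upsample: sum gradients over each 2x2 block.
// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dy) {
  const arma::uword H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (arma::uword ci = 0; ci < C; ++ci) {
    const arma::mat& d = dy.slice(ci);
    arma::mat& o = dx.slice(ci);
    for (arma::uword cc = 0; cc < W; ++cc)
      for (arma::uword rr = 0; rr < H; ++rr)
        o(rr, cc) = d(2 * rr, 2 * cc) + d(2 * rr + 1, 2 * cc) +
                    d(2 * rr, 2 * cc + 1) + d(2 * rr + 1, 2 * cc + 1);
  }
  return dx;
}
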