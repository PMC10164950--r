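// Low-level numerical kernels for the CPU neural-network engine and the
// image-processing primitives. Feature maps are H x W x C arma::cubes,
// mapping directly onto R arrays with dim = c(H, W, C).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col / col2im for stride-1 dilated 2-D convolution with zero padding.
// Column layout: j = ci*k*k + kr*k + kc; row layout: p = r + c*H (col-major).
// ---------------------------------------------------------------------------
static arma::mat im2col(const arma::cube& x, int k, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube xp(H + 2 * pad, W + 2 * pad, C, arma::fill::zeros);
  xp.subcube(pad, pad, 0, pad + H - 1, pad + W - 1, C - 1) = x;
  arma::mat col(static_cast<arma::uword>(H) * W, static_cast<arma::uword>(C) * k * k);
  for (int ci = 0; ci < C; ++ci)
    for (int kr = 0; kr < k; ++kr)
      for (int kc = 0; kc < k; ++kc) {
        int j = ci * k * k + kr * k + kc;
        col.col(j) = arma::vectorise(
          xp.slice(ci).submat(kr * dil, kc * dil, kr * dil + H - 1, kc * dil + W - 1));
      }
  return col;
}

static arma::cube col2im(const arma::mat& col, int H, int W, int C,
                         int k, int pad, int dil) {
  arma::cube xp(H + 2 * pad, W + 2 * pad, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int kr = 0; kr < k; ++kr)
      for (int kc = 0; kc < k; ++kc) {
        int j = ci * k * k + kr * k + kc;
        xp.slice(ci).submat(kr * dil, kc * dil, kr * dil + H - 1, kc * dil + W - 1) +=
          arma::reshape(col.col(j), H, W);
      }
  return xp.subcube(pad, pad, 0, pad + H - 1, pad + W - 1, C - 1);
}

// y = conv2d(x, w) + b; w is (Cin*k*k) x Cout, stride 1, 'same' output size.
// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat y;
  if (k == 1 && pad == 0) {
    // 1x1 convolution: plain GEMM on the flattened map, no im2col copy.
    arma::mat xm(const_cast<double*>(x.memptr()),
                 static_cast<arma::uword>(H) * W, x.n_slices, false, true);
    y = xm * w;
  } else {
    y = im2col(x, k, pad, dil) * w;
  }
  y.each_row() += b.t();
  return arma::cube(y.memptr(), H, W, Cout);
}

// Gradients of conv2d wrt input, weight and bias.
// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::mat& w,
                   const arma::cube& gy, int k, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gym(const_cast<double*>(gy.memptr()),
                static_cast<arma::uword>(H) * W, Cout, false, true);
  arma::mat gw;
  arma::cube gx;
  if (k == 1 && pad == 0) {
    arma::mat xm(const_cast<double*>(x.memptr()),
                 static_cast<arma::uword>(H) * W, Cin, false, true);
    gw = xm.t() * gym;
    arma::mat gxm = gym * w.t();
    gx = arma::cube(gxm.memptr(), H, W, Cin);
  } else {
    arma::mat col = im2col(x, k, pad, dil);
    gw = col.t() * gym;
    arma::mat gcol = gym * w.t();
    gx = col2im(gcol, H, W, Cin, k, pad, dil);
  }
  arma::vec gb = arma::sum(gym, 0).t();
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2, ceil mode (odd trailing rows/cols kept).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = (H + 1) / 2, ow = (W + 1) / 2;
  arma::cube y(oh, ow, C);
  arma::ucube idx(oh, ow, C);  // linear index into the input slice
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& s = x.slice(ci);
    for (int oc = 0; oc < ow; ++oc)
      for (int orow = 0; orow < oh; ++orow) {
        int r0 = 2 * orow, c0 = 2 * oc;
        int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        double best = s(r0, c0);
        arma::uword bi = r0 + static_cast<arma::uword>(c0) * H;
        if (s(r1, c0) > best) { best = s(r1, c0); bi = r1 + static_cast<arma::uword>(c0) * H; }
        if (s(r0, c1) > best) { best = s(r0, c1); bi = r0 + static_cast<arma::uword>(c1) * H; }
        if (s(r1, c1) > best) { best = s(r1, c1); bi = r1 + static_cast<arma::uword>(c1) * H; }
        y(orow, oc, ci) = best;
        idx(orow, oc, ci) = bi;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::cube& gy, const arma::ucube& idx,
                           int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    double* gs = gx.slice(ci).memptr();
    for (arma::uword j = 0; j < gy.n_rows * gy.n_cols; ++j)
      gs[idx.slice(ci)(j)] += gy.slice(ci)(j);
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Bilinear resize (align_corners = FALSE convention) with exact adjoint.
// ---------------------------------------------------------------------------
static inline void bil_coef(int o, int n_in, int n_out, int& i0, int& i1, double& w1) {
  double src = (o + 0.5) * (static_cast<double>(n_in) / n_out) - 0.5;
  if (src < 0) src = 0;
  if (src > n_in - 1) src = n_in - 1;
  i0 = static_cast<int>(std::floor(src));
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = src - i0;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(oh, ow, C);
  std::vector<int> r0(oh), r1(oh), c0(ow), c1(ow);
  std::vector<double> wr(oh), wc(ow);
  for (int i = 0; i < oh; ++i) bil_coef(i, H, oh, r0[i], r1[i], wr[i]);
  for (int j = 0; j < ow; ++j) bil_coef(j, W, ow, c0[j], c1[j], wc[j]);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& s = x.slice(ci);
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double top = (1 - wc[j]) * s(r0[i], c0[j]) + wc[j] * s(r0[i], c1[j]);
        double bot = (1 - wc[j]) * s(r1[i], c0[j]) + wc[j] * s(r1[i], c1[j]);
        y(i, j, ci) = (1 - wr[i]) * top + wr[i] * bot;
      }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_bw(const arma::cube& gy, int ih, int iw) {
  const int oh = gy.n_rows, ow = gy.n_cols, C = gy.n_slices;
  arma::cube gx(ih, iw, C, arma::fill::zeros);
  std::vector<int> r0(oh), r1(oh), c0(ow), c1(ow);
  std::vector<double> wr(oh), wc(ow);
  for (int i = 0; i < oh; ++i) bil_coef(i, ih, oh, r0[i], r1[i], wr[i]);
  for (int j = 0; j < ow; ++j) bil_coef(j, iw, ow, c0[j], c1[j], wc[j]);
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& g = gx.slice(ci);
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double v = gy(i, j, ci);
        g(r0[i], c0[j]) += (1 - wr[i]) * (1 - wc[j]) * v;
        g(r0[i], c1[j]) += (1 - wr[i]) * wc[j] * v;
        g(r1[i], c0[j]) += wr[i] * (1 - wc[j]) * v;
        g(r1[i], c1[j]) += wr[i] * wc[j] * v;
      }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Windowed resampling used by augmentation: tile pixel (i,j) samples the
// source at ((off + i + 0.5)/scale - 0.5) so that scale-then-crop never
// materializes the full scaled image.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::cube cpp_window_bilinear(const arma::cube& x, int oh, int ow,
                               double scale, double off_r, double off_c) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(oh, ow, C);
  auto coef = [](double src, int n, int& i0, int& i1, double& w1) {
    if (src < 0) src = 0;
    if (src > n - 1) src = n - 1;
    i0 = static_cast<int>(std::floor(src));
    i1 = std::min(i0 + 1, n - 1);
    w1 = src - i0;
  };
  for (int j = 0; j < ow; ++j) {
    int c0, c1; double wc;
    coef((off_c + j + 0.5) / scale - 0.5, W, c0, c1, wc);
    for (int i = 0; i < oh; ++i) {
      int r0, r1; double wr;
      coef((off_r + i + 0.5) / scale - 0.5, H, r0, r1, wr);
      for (int ci = 0; ci < C; ++ci) {
        const arma::mat& s = x.slice(ci);
        double top = (1 - wc) * s(r0, c0) + wc * s(r0, c1);
        double bot = (1 - wc) * s(r1, c0) + wc * s(r1, c1);
        y(i, j, ci) = (1 - wr) * top + wr * bot;
      }
    }
  }
  return y;
}

// Nearest-neighbour companion (used for masks; keeps values binary).
// [[Rcpp::export]]
arma::imat cpp_window_nearest(const arma::imat& m, int oh, int ow,
                              double scale, double off_r, double off_c) {
  const int H = m.n_rows, W = m.n_cols;
  arma::imat y(oh, ow);
  for (int j = 0; j < ow; ++j) {
    int sc = static_cast<int>(std::floor((off_c + j + 0.5) / scale));
    sc = std::max(0, std::min(sc, W - 1));
    for (int i = 0; i < oh; ++i) {
      int sr = static_cast<int>(std::floor((off_r + i + 0.5) / scale));
      sr = std::max(0, std::min(sr, H - 1));
      y(i, j) = m(sr, sc);
    }
  }
  return y;
}

// ---------------------------------------------------------------------------
// Non-local means denoising, per channel: each pixel is replaced by a
// similarity-weighted average over a search window, weights
// exp(-mean patch SSD / h^2). Borders handled by coordinate clamping.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::cube cpp_nlm_denoise(const arma::cube& x, double h, int patch, int search) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pr = patch / 2, sr = search / 2;
  const double h2 = std::max(h * h, 1e-12);
  arma::cube y(H, W, C);
  auto cl = [](int v, int n) { return std::max(0, std::min(v, n - 1)); };
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& s = x.slice(ci);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double wsum = 0, vsum = 0;
        for (int dc = -sr; dc <= sr; ++dc)
          for (int dr = -sr; dr <= sr; ++dr) {
            int rr = cl(r + dr, H), cc = cl(c + dc, W);
            double d2 = 0;
            for (int pc = -pr; pc <= pr; ++pc)
              for (int prr = -pr; prr <= pr; ++prr) {
                double a = s(cl(r + prr, H), cl(c + pc, W));
                double b = s(cl(rr + prr, H), cl(cc + pc, W));
                d2 += (a - b) * (a - b);
              }
            d2 /= static_cast<double>(patch) * patch;
            double w = std::exp(-d2 / h2);
            wsum += w;
            vsum += w * s(rr, cc);
          }
        y(r, c, ci) = vsum / wsum;
      }
  }
  return y;
}

// ---------------------------------------------------------------------------
// Connected-component labeling (4- or 8-connectivity) with min-size filter.
// Labels are 1..K in first-encounter (column-major scan) order after
// filtering; background 0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity,
                                   int min_size) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> sizes;  // sizes[k-1] = pixel count of provisional label k
  std::vector<std::pair<int, int>> stack;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      int count = 0;
      stack.clear();
      stack.emplace_back(r, c);
      lab(r, c) = next;
      while (!stack.empty()) {
        auto [cr, cc] = stack.back();
        stack.pop_back();
        ++count;
        for (int t = 0; t < nn; ++t) {
          int nr = cr + dr8[t], nc = cc + dc8[t];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.emplace_back(nr, nc);
          }
        }
      }
      sizes.push_back(count);
    }
  // Filter small components and renumber compactly.
  std::vector<int> remap(next + 1, 0);
  int keep = 0;
  for (int k = 1; k <= next; ++k)
    if (sizes[k - 1] >= min_size) remap[k] = ++keep;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) lab(r, c) = remap[lab(r, c)];
  lab.attr("n_components") = keep;
  return lab;
}
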