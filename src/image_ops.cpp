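// Low-level raster primitives: block-mean downsampling and connected
// component labeling. Kept in C++ because they run on full-resolution
// slide rasters.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Block-mean downsample of an RGB cube by an integer factor.
// Output dimensions are ceil(input / factor); partial edge blocks average
// over the pixels present.
// [[Rcpp::export]]
arma::cube cpp_block_downsample(const arma::cube& img, const int factor) {
  if (factor < 1) stop("factor must be >= 1");
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  const int h = (H + factor - 1) / factor, w = (W + factor - 1) / factor;
  arma::cube out(h, w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int bi = 0; bi < h; ++bi) {
      const int r0 = bi * factor, r1 = std::min(H, r0 + factor);
      for (int bj = 0; bj < w; ++bj) {
        const int c0 = bj * factor, c1 = std::min(W, c0 + factor);
        double s = 0.0;
        for (int i = r0; i < r1; ++i)
          for (int j = c0; j < c1; ++j) s += img(i, j, c);
        out(bi, bj, c) = s / ((r1 - r0) * (c1 - c0));
      }
    }
  }
  return out;
}

// Label connected components of a binary mask (row-major BFS).
// connectivity is 4 or 8. Labels are 1..n in discovery order (row-major
// scan), 0 for background; this fixes the tie-break used downstream.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask,
                                   const int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          const int r = p.first + dr[k], c = p.second + dc[k];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (mask(r, c) && lab(r, c) == 0) {
            lab(r, c) = next;
            q.push(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}

// Paint filled discs (value `value`) into a numeric matrix, in place
// semantics avoided: returns a modified copy. Centers are 0-based (row, col);
// membership rule is ||p - c|| <= radius on pixel centers.
// [[Rcpp::export]]
NumericMatrix cpp_paint_discs(const NumericMatrix& canvas,
                              const NumericMatrix& centers,
                              const double radius, const double value) {
  NumericMatrix out = clone(canvas);
  const int H = out.nrow(), W = out.ncol();
  const double r2 = radius * radius;
  for (int k = 0; k < centers.nrow(); ++k) {
    const double cr = centers(k, 0), cc = centers(k, 1);
    const int lo_r = std::max(0, (int)std::floor(cr - radius));
    const int hi_r = std::min(H - 1, (int)std::ceil(cr + radius));
    const int lo_c = std::max(0, (int)std::floor(cc - radius));
    const int hi_c = std::min(W - 1, (int)std::ceil(cc + radius));
    for (int i = lo_r; i <= hi_r; ++i)
      for (int j = lo_c; j <= hi_c; ++j)
        if ((i - cr) * (i - cr) + (j - cc) * (j - cc) <= r2)
          out(i, j) = value;
  }
  return out;
}
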