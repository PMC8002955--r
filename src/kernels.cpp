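#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline void sort2(double& a, double& b) { if (a > b) std::swap(a, b); }

// median of 9 via the classic 19-exchange network
static inline double med9(double p[9]) {
  sort2(p[1], p[2]); sort2(p[4], p[5]); sort2(p[7], p[8]);
  sort2(p[0], p[1]); sort2(p[3], p[4]); sort2(p[6], p[7]);
  sort2(p[1], p[2]); sort2(p[4], p[5]); sort2(p[7], p[8]);
  sort2(p[0], p[3]); sort2(p[5], p[8]); sort2(p[4], p[7]);
  sort2(p[3], p[6]); sort2(p[1], p[4]); sort2(p[2], p[5]);
  sort2(p[4], p[7]); sort2(p[4], p[2]); sort2(p[6], p[4]);
  sort2(p[4], p[2]);
  return p[4];
}

// Median filter with selectable border padding.
// kernel must be odd; pad_mode: 0 = edge replication, 1 = zero padding.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, int kernel, int pad_mode) {
  const int H = img.nrow(), W = img.ncol(), r = kernel / 2;
  const int PH = H + 2 * r, PW = W + 2 * r;
  std::vector<double> padded((size_t) PH * PW, 0.0);
  for (int j = 0; j < PW; ++j) {
    int jj = j - r;
    bool outc = (jj < 0 || jj >= W);
    if (pad_mode == 0) jj = std::min(std::max(jj, 0), W - 1);
    for (int i = 0; i < PH; ++i) {
      int ii = i - r;
      bool outr = (ii < 0 || ii >= H);
      if (pad_mode == 1 && (outc || outr)) continue;  // stays zero
      if (pad_mode == 0) ii = std::min(std::max(ii, 0), H - 1);
      padded[(size_t) j * PH + i] = img(ii, jj);
    }
  }
  NumericMatrix out(H, W);
  const int k2 = kernel * kernel;
  if (kernel == 3) {
    double p[9];
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int n = 0;
        for (int dj = 0; dj < 3; ++dj)
          for (int di = 0; di < 3; ++di)
            p[n++] = padded[(size_t)(j + dj) * PH + i + di];
        out(i, j) = med9(p);
      }
    }
  } else {
    std::vector<double> buf(k2);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int n = 0;
        for (int dj = 0; dj < kernel; ++dj)
          for (int di = 0; di < kernel; ++di)
            buf[n++] = padded[(size_t)(j + dj) * PH + i + di];
        std::nth_element(buf.begin(), buf.begin() + k2 / 2, buf.end());
        out(i, j) = buf[k2 / 2];
      }
    }
  }
  return out;
}

// Connected-component labeling of a logical mask, 4- or 8-connectivity.
// Labels start at 1 in scan order (down columns, then across); 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < nn; ++k) {
          int ii = p.first + dr[k], jj = p.second + dc[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// ImageJ-wand-style tolerance selection: maximal 8-connected region around
// the seed whose values differ from the seed value by at most tol.
// [[Rcpp::export]]
LogicalMatrix wand_select_cpp(const NumericMatrix& img, int seed_row, int seed_col,
                              double tol) {
  const int H = img.nrow(), W = img.ncol();
  LogicalMatrix mask(H, W);
  std::fill(mask.begin(), mask.end(), false);
  const double v0 = img(seed_row, seed_col);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::queue<std::pair<int, int> > q;
  mask(seed_row, seed_col) = true;
  q.push(std::make_pair(seed_row, seed_col));
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int k = 0; k < 8; ++k) {
      int ii = p.first + dr[k], jj = p.second + dc[k];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      if (!mask(ii, jj) && std::abs(img(ii, jj) - v0) <= tol) {
        mask(ii, jj) = true;
        q.push(std::make_pair(ii, jj));
      }
    }
  }
  return mask;
}
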