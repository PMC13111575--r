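#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-pixel median filter with a spatially varying odd window size.
// Windows are clipped at image borders (no padding) and the lower median
// is taken, so every output value is attained in the input window.
// [[Rcpp::export(name = ".ceamf_median")]]
IntegerMatrix ceamf_median(const IntegerMatrix& img, const IntegerMatrix& win) {
  const int nr = img.nrow(), nc = img.ncol();
  if (win.nrow() != nr || win.ncol() != nc)
    stop("window-size map must match image dimensions");
  IntegerMatrix out(nr, nc);
  std::vector<int> buf;
  for (int i = 0; i < nc; ++i) {
    for (int j = 0; j < nr; ++j) {
      const int u = win(j, i);
      if (u < 1 || u % 2 == 0) stop("window sizes must be odd and >= 1");
      const int h = (u - 1) / 2;
      const int r0 = std::max(0, j - h), r1 = std::min(nr - 1, j + h);
      const int c0 = std::max(0, i - h), c1 = std::min(nc - 1, i + h);
      buf.clear();
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r)
          buf.push_back(img(r, c));
      const int k = (static_cast<int>(buf.size()) - 1) / 2;  // lower median
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(j, i) = buf[k];
    }
  }
  return out;
}

// 8-connected component labeling of a logical matrix (iterative flood fill).
// Labels are positive integers in scan order; background stays 0.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int i = 0; i < nc; ++i) {
    for (int j = 0; j < nr; ++j) {
      if (!mask(j, i) || lab(j, i) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(j, i));
      lab(j, i) = next;
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int r = p.first + dr, c = p.second + dc;
            if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
            if (mask(r, c) && lab(r, c) == 0) {
              lab(r, c) = next;
              stack.push_back(std::make_pair(r, c));
            }
          }
        }
      }
    }
  }
  return lab;
}
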