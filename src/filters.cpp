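// Spatial filters with symmetric (reflect) boundary handling, matching the
// documented preprocessing contract exactly: separable Gaussian truncated at
// ceil(3*sigma), and a median filter over a square window of side 2r+1.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {
// symmetric reflection (edge included): ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}
} // namespace

// [[Rcpp::export]]
NumericMatrix gaussian_filter_cpp(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double& k : kern) k /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) // along rows (vertical)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += kern[t + r] * img(reflect(i + t, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j) // along columns (horizontal)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) acc += kern[t + r] * tmp(i, reflect(j + t, nc));
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  if (radius <= 0) return clone(img);
  NumericMatrix out(nr, nc);
  const int side = 2 * radius + 1;
  std::vector<double> win((size_t)side * side);
  const size_t mid = win.size() / 2; // odd count: median is an element
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      size_t t = 0;
      for (int dj = -radius; dj <= radius; ++dj)
        for (int di = -radius; di <= radius; ++di)
          win[t++] = img(reflect(i + di, nr), reflect(j + dj, nc));
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      out(i, j) = win[mid];
    }
  return out;
}
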