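// square-window median filter on one padded channel; returns the core
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// padded: (h + 2p) x (w + 2p) matrix; returns h x w median-filtered core
// [[Rcpp::export]]
NumericMatrix cpp_median_core(const NumericMatrix& padded, int p) {
  const int hp = padded.nrow(), wp = padded.ncol();
  const int h = hp - 2 * p, w = wp - 2 * p;
  const int win = 2 * p + 1, k = win * win;
  NumericMatrix out(h, w);
  std::vector<double> buf(k);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int t = 0;
      for (int dj = 0; dj < win; ++dj)
        for (int di = 0; di < win; ++di)
          buf[t++] = padded(i + di, j + dj);
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}
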