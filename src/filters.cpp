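// Classical per-slice filters used by the conversion baselines.
// Edges are handled by symmetric (mirror) reflection.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// separable Gaussian with per-axis sigma (in voxels)
// [[Rcpp::export]]
arma::mat gaussian_blur_cpp(const arma::mat& X, double sig_r, double sig_c) {
  int nr = X.n_rows, nc = X.n_cols;
  mat tmp = X, out = X;
  if (sig_r > 0) {
    int h = std::max(1, (int)std::ceil(3.0 * sig_r));
    vec k(2 * h + 1);
    for (int i = -h; i <= h; i++) k(i + h) = std::exp(-0.5 * i * i / (sig_r * sig_r));
    k /= accu(k);
    for (int c = 0; c < nc; c++) {
      for (int r = 0; r < nr; r++) {
        double s = 0;
        for (int i = -h; i <= h; i++) s += k(i + h) * X(reflect_idx(r + i, nr), c);
        tmp(r, c) = s;
      }
    }
  }
  if (sig_c > 0) {
    int h = std::max(1, (int)std::ceil(3.0 * sig_c));
    vec k(2 * h + 1);
    for (int i = -h; i <= h; i++) k(i + h) = std::exp(-0.5 * i * i / (sig_c * sig_c));
    k /= accu(k);
    for (int r = 0; r < nr; r++) {
      for (int c = 0; c < nc; c++) {
        double s = 0;
        for (int i = -h; i <= h; i++) s += k(i + h) * tmp(r, reflect_idx(c + i, nc));
        out(r, c) = s;
      }
    }
  } else {
    out = tmp;
  }
  return out;
}

// square-window median filter of radius `rad` (window (2*rad+1)^2)
// [[Rcpp::export]]
arma::mat median_filter_cpp(const arma::mat& X, int rad) {
  int nr = X.n_rows, nc = X.n_cols;
  mat out(nr, nc);
  int wlen = (2 * rad + 1) * (2 * rad + 1);
  std::vector<double> buf(wlen);
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      int k = 0;
      for (int dc = -rad; dc <= rad; dc++) {
        int cc = reflect_idx(c + dc, nc);
        for (int dr = -rad; dr <= rad; dr++) {
          buf[k++] = X(reflect_idx(r + dr, nr), cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + wlen / 2, buf.begin() + wlen);
      double med = buf[wlen / 2];
      if (wlen % 2 == 0) {
        // not reachable for odd windows, kept for completeness
        std::nth_element(buf.begin(), buf.begin() + wlen / 2 - 1,
                         buf.begin() + wlen);
        med = 0.5 * (med + buf[wlen / 2 - 1]);
      }
      out(r, c) = med;
    }
  }
  return out;
}
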