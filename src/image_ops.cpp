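#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Grayscale morphology: neighborhood max (dilate) or min (erode) over the
// true cells of a structuring element, anchor at center, edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_morph(const NumericMatrix& img, const LogicalMatrix& se,
                        bool dilate) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = se.nrow(), kw = se.ncol();
  const int ah = kh / 2, aw = kw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = dilate ? R_NegInf : R_PosInf;
      for (int dj = 0; dj < kw; ++dj) {
        const int jj = clampi(j + dj - aw, 0, W - 1);
        for (int di = 0; di < kh; ++di) {
          if (!se(di, dj)) continue;
          const int ii = clampi(i + di - ah, 0, H - 1);
          const double x = img(ii, jj);
          if (dilate ? (x > v) : (x < v)) v = x;
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// k x k neighborhood median, edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int k) {
  const int H = img.nrow(), W = img.ncol();
  const int a = k / 2, n = k * k;
  NumericMatrix out(H, W);
  std::vector<double> buf(n);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int dj = -a; dj <= a; ++dj) {
        const int jj = clampi(j + dj, 0, W - 1);
        for (int di = -a; di <= a; ++di) {
          const int ii = clampi(i + di, 0, H - 1);
          buf[m++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.end());
        med = 0.5 * (med + buf[n / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Separable convolution with a 1-D kernel applied along rows then columns,
// edge replication at the borders. Kernel length must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(const NumericMatrix& img, const NumericVector& kern) {
  const int H = img.nrow(), W = img.ncol();
  const int k = kern.size(), a = k / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // vertical pass
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -a; d <= a; ++d) s += kern[d + a] * img(clampi(i + d, 0, H - 1), j);
      tmp(i, j) = s;
    }
  // horizontal pass
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -a; d <= a; ++d) s += kern[d + a] * tmp(i, clampi(j + d, 0, W - 1));
      out(i, j) = s;
    }
  return out;
}
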