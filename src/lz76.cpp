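#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv (1976) production complexity c(n) of a binary sequence,
// Kaspar-Schuster scan. Returns the number of phrases in the exhaustive
// production history.
static int lz76_count(const std::vector<int> &s) {
  const int n = (int)s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  while (true) {
    if (l + k > n) { // reached the end while copying: final phrase
      c++;
      break;
    }
    if (s[i + k - 1] == s[l + k - 1]) {
      k++;
      if (l + k - 1 > n) { c++; break; }
    } else {
      if (k > k_max) k_max = k;
      i++;
      if (i == l) { // no longer substring: new phrase
        c++;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// [[Rcpp::export(name = ".lz76_binary")]]
int lz76_binary(IntegerVector bits) {
  std::vector<int> s(bits.begin(), bits.end());
  return lz76_count(s);
}

// Median-binarize each column of x and return the LZ76 phrase count per
// column. Used by the Kolmogorov-complexity feature on many epochs at once.
// [[Rcpp::export(name = ".lz76_columns")]]
IntegerVector lz76_columns(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  IntegerVector out(m);
  std::vector<double> buf(n);
  std::vector<int> s(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    std::vector<double> tmp(buf);
    std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.end());
    double med = tmp[n / 2];
    if (n % 2 == 0) {
      std::nth_element(tmp.begin(), tmp.begin() + n / 2 - 1, tmp.end());
      med = 0.5 * (med + tmp[n / 2 - 1]);
    }
    for (int i = 0; i < n; ++i) s[i] = buf[i] > med ? 1 : 0;
    out[j] = lz76_count(s);
  }
  return out;
}
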