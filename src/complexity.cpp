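#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy with an embedding lag.
// Templates start at i = 0..N-1 with N = n - m*lag, so that every
// template has both an m-point and an (m+1)-point extension; matches use
// the Chebyshev distance and exclude self-matches (i < j only).
// Returns c(B, A): B = m-point matches, A = (m+1)-point matches.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, int lag, double r) {
  int n = x.size();
  int N = n - m * lag;
  if (N < 2) return NumericVector::create(0.0, 0.0);
  // Sort template starts by their first coordinate: only pairs within r
  // on that coordinate can match, so a sorted sweep prunes most pairs.
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double A = 0.0, B = 0.0;
  for (int p = 0; p < N - 1; ++p) {
    int i = ord[p];
    double xi = x[i];
    for (int q = p + 1; q < N; ++q) {
      int j = ord[q];
      if (x[j] - xi > r) break;
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k * lag] - x[j + k * lag]) > r) {
          match = false;
          break;
        }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m * lag] - x[j + m * lag]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// LZ76 exhaustive-history word count (Kaspar & Schuster 1987) on an
// integer symbol sequence; the terminal word is counted whether or not
// it completes. A constant sequence therefore parses to 2 words for
// n >= 2 (the first symbol, then one never-terminating reproduction).
// [[Rcpp::export(name = ".lz76_cpp")]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n <= 1) return n;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
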