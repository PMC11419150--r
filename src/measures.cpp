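#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Counts of template matches for sample entropy at orders m and m+1,
// Chebyshev distance, self-matches excluded.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  double a = 0.0; // matches of length m + 1
  double b = 0.0; // matches of length m
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        b += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm > d) d = dm;
        if (d <= r) a += 1.0;
      }
    }
  }
  return NumericVector::create(a, b);
}

// Approximate entropy: phi(m) - phi(m+1), self-matches included.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int nt = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double dk = std::fabs(x[i + k] - x[j + k]);
          if (dk > d) d = dk;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / nt);
    }
    phi[s] = acc / nt;
  }
  return phi[0] - phi[1];
}

// Higuchi mean normalized curve lengths L(k) for k = 1..kmax.
// [[Rcpp::export]]
NumericVector higuchi_lengths_cpp(NumericVector x, int kmax) {
  int n = x.size();
  NumericVector lk(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double lsum = 0.0;
    for (int m = 0; m < k; ++m) {
      int nm = (n - 1 - m) / k; // number of steps in this subseries
      if (nm < 1) continue;
      double len = 0.0;
      for (int i = 1; i <= nm; ++i) {
        len += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      }
      // normalization: (n - 1) / (nm * k) per Higuchi's definition
      lsum += len * (double)(n - 1) / ((double)nm * k) / k;
    }
    lk[k - 1] = lsum / k;
  }
  return lk;
}

// LZ76 parsing (Kaspar & Schuster scheme): number of phrases in a binary
// (0/1) sequence.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1;    // phrase count
  int l = 1;    // start (1-based) of the phrase being parsed
  int i = 0;    // candidate match start within the prefix
  int k = 1;    // current extension length
  int kmax = 1; // longest extension found from any candidate
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) { // no candidate reproduces the phrase: new phrase
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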