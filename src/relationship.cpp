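#include <Rcpp.h>
using namespace Rcpp;

// Pedigree codes are 1-based and topologically ordered (parents precede
// offspring); 0 marks an unknown parent.

// Meuwissen & Luo style recursion: f_i = a_ii - 1 with a_ii accumulated from
// the L D L' decomposition of A, tracing only the ancestors of i. Mendelian
// sampling variances use f = -1 for unknown parents, which folds the
// one-/zero-known-parent adjustments into a single expression.
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector f(n);
  std::vector<double> dms(n), L(n);
  for (int i = 0; i < n; i++) {
    int s = sire[i], d = dam[i];
    if (s > i || d > i)
      stop("pedigree not topologically ordered at position %d", i + 1);
    double fs = s ? f[s - 1] : -1.0;
    double fd = d ? f[d - 1] : -1.0;
    dms[i] = 0.5 - 0.25 * (fs + fd);
    if (!s || !d) { f[i] = 0.0; continue; }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double fi = -1.0;
    for (int j = i; j >= 0; j--) {
      double lj = L[j];
      if (lj == 0.0) continue;
      fi += lj * lj * dms[j];
      if (sire[j]) L[sire[j] - 1] += 0.5 * lj;
      if (dam[j])  L[dam[j] - 1]  += 0.5 * lj;
    }
    f[i] = fi;
  }
  return f;
}

// Dense numerator relationship matrix by the tabular (recursive) method.
// [[Rcpp::export]]
NumericMatrix tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; i++) {
    int s = sire[i], d = dam[i];
    if (s > i || d > i)
      stop("pedigree not topologically ordered at position %d", i + 1);
    for (int j = 0; j < i; j++) {
      double v = 0.0;
      if (s) v += 0.5 * A(j, s - 1);
      if (d) v += 0.5 * A(j, d - 1);
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + (s && d ? 0.5 * A(s - 1, d - 1) : 0.0);
  }
  return A;
}
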