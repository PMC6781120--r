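#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Selected inverse (Takahashi equations) of a sparse SPD matrix given its
// simplicial Cholesky factor L (C = L L', lower triangular, CSC slots with
// row indices sorted within each column, diagonal first). Returns the
// values of inv(C) on the pattern of L (lower triangle including the
// diagonal), in the same CSC layout. Entries of inv(C) outside the fill
// pattern are not computed; every entry on the pattern of C itself is
// covered because the factor's pattern contains it.
//
// Recurrences, processing columns j = n-1 .. 0 with I = struct(L[,j]) \ {j}:
//   S[i,j] = -(1/L[j,j]) * sum_{k in I} L[k,j] * S[max(k,i), min(k,i)]
//   S[j,j] = 1/L[j,j]^2 - (1/L[j,j]) * sum_{k in I} L[k,j] * S[k,j]
// The inner sums are accumulated over symmetric pairs (i <= k, both in I)
// by scattering column i of the partial inverse into a stamped dense
// workspace, which avoids per-entry searches. The fill-path closure of the
// factor guarantees that every needed entry lies on the pattern.
// [[Rcpp::export(name = ".takahashi_inverse")]]
NumericVector takahashi_inverse(IntegerVector Lp, IntegerVector Li,
                                NumericVector Lx, int n) {
  NumericVector Sx(Lx.size());
  std::vector<double> work(n, 0.0);
  std::vector<int> stamp(n, -1);
  std::vector<double> acc;
  int tick = 0;
  for (int j = n - 1; j >= 0; --j) {
    int cs = Lp[j], ce = Lp[j + 1];
    if (cs == ce) continue;
    double ljj = Lx[cs];            // diagonal-first storage
    int m = ce - cs - 1;            // off-diagonal count
    if (m == 0) {
      Sx[cs] = 1.0 / (ljj * ljj);
      continue;
    }
    acc.assign(m, 0.0);
    // symmetric-pair accumulation: for each i (ascending rows in I),
    // scatter column i of S and sweep k >= i within I
    for (int a = 0; a < m; ++a) {
      int i = Li[cs + 1 + a];
      double lij = Lx[cs + 1 + a];
      ++tick;  // one-shot stamp: no reset sweep needed
      for (int q = Lp[i]; q < Lp[i + 1]; ++q) {
        work[Li[q]] = Sx[q];
        stamp[Li[q]] = tick;
      }
      const int *rows = &Li[cs + 1];
      const double *vals = &Lx[cs + 1];
      double ai = acc[a];
      for (int b = a; b < m; ++b) {
        int k = rows[b];
        if (stamp[k] != tick) continue;
        double v = work[k];
        ai += vals[b] * v;
        if (b > a) acc[b] += lij * v;
      }
      acc[a] = ai;
    }
    double dot = 0.0;
    for (int a = 0; a < m; ++a) {
      double s = -acc[a] / ljj;
      Sx[cs + 1 + a] = s;
      dot += Lx[cs + 1 + a] * s;
    }
    Sx[cs] = 1.0 / (ljj * ljj) - dot / ljj;
  }
  return Sx;
}
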