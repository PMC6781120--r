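#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo recursion.
// sire/dam are 0-based row indices into the (topologically sorted)
// pedigree, or -1 when unknown.
// d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d), dropping the term of an unknown
// parent; a_ii = sum_j L_ij^2 d_j traced back from i; F_i = a_ii - 1.
// [[Rcpp::export(name = ".ml_inbreeding")]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n);
  std::vector<double> v(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], m = dam[i];
    d[i] = 1.0;
    if (s >= 0) d[i] -= 0.25 * (1.0 + F[s]);
    if (m >= 0) d[i] -= 0.25 * (1.0 + F[m]);
    if (s < 0 && m < 0) { F[i] = 0.0; continue; }
    std::fill(v.begin(), v.begin() + i + 1, 0.0);
    v[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      double c = v[j];
      if (c == 0.0) continue;
      aii += c * c * d[j];
      if (sire[j] >= 0) v[sire[j]] += 0.5 * c;
      if (dam[j] >= 0)  v[dam[j]]  += 0.5 * c;
    }
    F[i] = aii - 1.0;
  }
  return F;
}
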