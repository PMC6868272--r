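#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) inbreeding coefficients.
// sire, dam: 1-based positions of parents in a topologically sorted
// pedigree, 0 = unknown. Founders (or anyone with a missing parent
// treated as unrelated) get F = 0.
// For individual i, a_ii = 1 + F_i = sum_j L_j^2 d_j over ancestors j,
// where L_j is the expected genetic contribution of j to i and d_j the
// Mendelian-sampling variance d_j = 0.5 - 0.25 (F_sj + F_dj) with the
// convention F = -1 for an unknown parent.
// [[Rcpp::export(name = ".ml_inbreeding")]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), d(n);
  std::vector<double> L(n + 1);
  for (int i = 0; i < n; ++i) {
    double Fs = sire[i] > 0 ? F[sire[i] - 1] : -1.0;
    double Fd = dam[i]  > 0 ? F[dam[i] - 1]  : -1.0;
    d[i] = 0.5 - 0.25 * (Fs + Fd);
    if (sire[i] == 0 || dam[i] == 0) { F[i] = 0.0; continue; }
    // accumulate a_ii by tracing contributions back from i
    std::fill(L.begin(), L.begin() + i + 2, 0.0);
    L[i + 1] = 1.0;
    double aii = 0.0;
    for (int j = i + 1; j >= 1; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      int js = sire[j - 1], jd = dam[j - 1];
      if (js > 0) L[js] += 0.5 * lj;
      if (jd > 0) L[jd] += 0.5 * lj;
      aii += lj * lj * d[j - 1];
    }
    F[i] = aii - 1.0;
  }
  return F;
}
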