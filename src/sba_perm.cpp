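#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Greedy LD-independent top-SNP selection and set statistic, applied to
// every column of a score-statistic matrix (one column per phenotype
// permutation).
//
// kmat: u x R matrix of per-SNP 1-df score chi-squares over the union of
//       all set SNPs (selection key: larger = more significant).
// r2:   u x u genotype r^2 matrix over the same union.
// rows: 1-based row indices of this set's SNPs, pre-sorted by (bp, rsid)
//       so that index order is the deterministic tie-break for equal
//       statistics.
// crit: chi-square inclusion threshold, qchisq(1 - set_p, 1).
// set_r2: LD independence ceiling; set_max: cap on selected SNPs.
// mean_p: statistic = mean upper-tail p of the selected chi-squares
//         (TRUE) or their mean chi-square (FALSE). Converting only the
//         <= set_max selected values avoids a pchisq over the full
//         permutation matrix.
//
// Returns a 3 x R matrix: row 0 the set statistic (NA when nothing is
// selected), row 1 nsig (SNPs past the threshold), row 2 isig (selected).
// [[Rcpp::export]]
NumericMatrix sba_set_stats(const NumericMatrix& kmat,
                            const NumericMatrix& r2,
                            const IntegerVector& rows,
                            double crit, double set_r2, int set_max,
                            bool mean_p) {
  const int k = rows.size(), R = kmat.ncol();
  NumericMatrix out(3, R);
  std::vector<int> cand;
  std::vector<int> sel;   // union-level row indices of accepted SNPs
  cand.reserve(k);
  sel.reserve(set_max > 0 ? set_max : 1);
  for (int c = 0; c < R; ++c) {
    cand.clear();
    for (int t = 0; t < k; ++t) {
      const int i = rows[t] - 1;
      if (kmat(i, c) > crit) cand.push_back(i);
    }
    const int nsig = (int)cand.size();
    // descending chi-square (= ascending p), ties broken by row order
    std::stable_sort(cand.begin(), cand.end(),
                     [&](int a, int b) { return kmat(a, c) > kmat(b, c); });
    sel.clear();
    double sum = 0.0;
    for (size_t t = 0; t < cand.size() && (int)sel.size() < set_max; ++t) {
      const int i = cand[t];
      bool ok = true;
      for (size_t s = 0; s < sel.size(); ++s) {
        if (r2(i, sel[s]) >= set_r2) { ok = false; break; }
      }
      if (ok) {
        sel.push_back(i);
        sum += mean_p ? R::pchisq(kmat(i, c), 1.0, 0, 0) : kmat(i, c);
      }
    }
    out(0, c) = sel.empty() ? NA_REAL : sum / sel.size();
    out(1, c) = nsig;
    out(2, c) = (double)sel.size();
  }
  return out;
}
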