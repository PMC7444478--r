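#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Permutation engine for the distance-based separation test.
// Each permutation independently shuffles every gene's values across all
// samples (Fisher-Yates driven by R's RNG so set.seed() governs the
// stream), then recomputes
//   meanDist(WT_focal, KI_focal) - meanDist(WT_ref, KI_ref)
// where meanDist averages Euclidean distances over all cross-genotype
// sample pairs within a stage. Indices are 0-based.

// [[Rcpp::export(name = ".permSepStats")]]
NumericVector permSepStats(NumericMatrix expr, IntegerVector wf,
                           IntegerVector kf, IntegerVector wr,
                           IntegerVector kr, int nPerm) {
  const int nG = expr.nrow(), nS = expr.ncol();
  const int nWf = wf.size(), nKf = kf.size();
  const int nWr = wr.size(), nKr = kr.size();
  const int nPf = nWf * nKf, nPr = nWr * nKr;
  NumericVector out(nPerm);
  std::vector<double> row(nS), accF(nPf), accR(nPr);
  for (int p = 0; p < nPerm; ++p) {
    std::fill(accF.begin(), accF.end(), 0.0);
    std::fill(accR.begin(), accR.end(), 0.0);
    for (int g = 0; g < nG; ++g) {
      for (int s = 0; s < nS; ++s) row[s] = expr(g, s);
      for (int s = nS - 1; s > 0; --s) {
        int j = (int)(unif_rand() * (s + 1));
        if (j > s) j = s;
        std::swap(row[s], row[j]);
      }
      int idx = 0;
      for (int a = 0; a < nWf; ++a) {
        const double xa = row[wf[a]];
        for (int b = 0; b < nKf; ++b, ++idx) {
          const double d = xa - row[kf[b]];
          accF[idx] += d * d;
        }
      }
      idx = 0;
      for (int a = 0; a < nWr; ++a) {
        const double xa = row[wr[a]];
        for (int b = 0; b < nKr; ++b, ++idx) {
          const double d = xa - row[kr[b]];
          accR[idx] += d * d;
        }
      }
    }
    double mF = 0.0, mR = 0.0;
    for (int i = 0; i < nPf; ++i) mF += std::sqrt(accF[i]);
    for (int i = 0; i < nPr; ++i) mR += std::sqrt(accR[i]);
    out[p] = mF / nPf - mR / nPr;
  }
  return out;
}
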