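#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact greedy split search over all (feature, threshold) pairs for one tree
// node, on first/second-order gradient statistics. Thresholds are midpoints
// between consecutive distinct sorted values. Gain:
//   0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda)) - gamma
// Ties resolved to the lowest feature index, then the lowest threshold,
// by scanning features and thresholds in ascending order with a strict
// improvement test.
// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                    IntegerVector rows, double lambda, double gamma,
                    int min_leaf) {
  int nr = rows.size();
  int nf = X.ncol();
  double Gtot = 0.0, Htot = 0.0;
  for (int t = 0; t < nr; t++) { Gtot += g[rows[t]]; Htot += h[rows[t]]; }
  double parent = Gtot * Gtot / (Htot + lambda);

  bool found = false;
  int best_feat = -1;
  double best_thr = 0.0, best_gain = 0.0;

  std::vector<double> xv(nr), gv(nr), hv(nr);
  std::vector<int> ord(nr);

  for (int j = 0; j < nf; j++) {
    for (int t = 0; t < nr; t++) xv[t] = X(rows[t], j);
    for (int t = 0; t < nr; t++) ord[t] = t;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    double GL = 0.0, HL = 0.0;
    for (int t = 0; t < nr - 1; t++) {
      int a = ord[t];
      GL += g[rows[a]]; HL += h[rows[a]];
      double xl = xv[a], xr = xv[ord[t + 1]];
      if (xr <= xl) continue;                 // not a boundary between distinct values
      int nl = t + 1, nrr = nr - nl;
      if (nl < min_leaf || nrr < min_leaf) continue;
      double GR = Gtot - GL, HR = Htot - HL;
      double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                           - parent) - gamma;
      if (gain > best_gain + 1e-12 || (!found && gain > 1e-12)) {
        found = true;
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (xl + xr);
      }
    }
  }
  return List::create(_["found"] = found, _["feature"] = best_feat + 1,
                      _["threshold"] = best_thr, _["gain"] = best_gain);
}
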