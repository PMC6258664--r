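#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sample entropy, Chebyshev distance, self-matches excluded.
// B counts pairs of all n-m+1 m-length templates within r; A counts pairs
// of all n-m (m+1)-length templates within r. Both template sets are closed
// under series reversal, so SampEn(x) == SampEn(rev(x)) exactly.
// The pair scan sorts template start indices by their first coordinate so
// each inner loop only visits candidates with |x_i - x_j| <= r.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int ntb = n - m + 1;   // m-length template count
  int nta = n - m;       // (m+1)-length template count
  if (nta < 2 || r <= 0.0) return NA_REAL;
  std::vector<int> ord(ntb);
  for (int i = 0; i < ntb; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return x[a] < x[b]; });
  long long A = 0, B = 0;
  for (int p = 0; p < ntb; p++) {
    int i = ord[p];
    for (int q = p + 1; q < ntb; q++) {
      int j = ord[q];
      if (x[j] - x[i] > r) break;
      bool okm = true;
      for (int k = 1; k < m; k++) {
        if (std::abs(x[i + k] - x[j + k]) > r) { okm = false; break; }
      }
      if (!okm) continue;
      B++;
      if (i < nta && j < nta && std::abs(x[i + m] - x[j + m]) <= r) A++;
    }
  }
  // zero-count guard: cap at log of the number of length-m templates
  if (B == 0 || A == 0) return std::log((double)(n - m));
  return -std::log((double)A / (double)B);
}
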