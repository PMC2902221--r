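#include <Rcpp.h>
using namespace Rcpp;

// Exact least-squares segmentation of an ordered log2-ratio profile.
// cost(i, j) = within-segment sum of squared deviations of x[i..j-1]
// (0-based half-open), computed from prefix sums. Ties in the optimal
// placement are broken toward the leftmost (smallest index) candidate,
// which makes the output deterministic.

static inline double seg_cost(const std::vector<double>& S1,
                              const std::vector<double>& S2,
                              int i, int j) {
  double d = S1[j] - S1[i];
  return S2[j] - S2[i] - d * d / (j - i);
}

// Penalized optimal partitioning: minimise sum of segment costs +
// penalty * (number of segments). Returns 1-based segment start indices.
// [[Rcpp::export]]
IntegerVector dp_penalized_cpp(NumericVector x, double penalty) {
  int n = x.size();
  std::vector<double> S1(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; i++) {
    S1[i + 1] = S1[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  std::vector<double> F(n + 1, 0.0);
  std::vector<int> back(n + 1, 0);
  for (int j = 1; j <= n; j++) {
    double best = R_PosInf;
    int bi = 0;
    for (int i = 0; i < j; i++) {
      double c = F[i] + seg_cost(S1, S2, i, j) + penalty;
      if (c < best - 1e-12) {  // strict improvement keeps the leftmost tie
        best = c;
        bi = i;
      }
    }
    F[j] = best;
    back[j] = bi;
  }
  std::vector<int> starts;
  for (int j = n; j > 0; j = back[j]) starts.push_back(back[j] + 1);
  std::reverse(starts.begin(), starts.end());
  return wrap(starts);
}

// Optimal segmentation into exactly k segments (k <= n).
// Returns 1-based segment start indices.
// [[Rcpp::export]]
IntegerVector dp_fixedk_cpp(NumericVector x, int k) {
  int n = x.size();
  if (k > n) k = n;
  std::vector<double> S1(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; i++) {
    S1[i + 1] = S1[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  // D[m][j]: best cost of splitting x[0..j) into m segments
  std::vector<std::vector<double>> D(k + 1, std::vector<double>(n + 1, R_PosInf));
  std::vector<std::vector<int>> B(k + 1, std::vector<int>(n + 1, 0));
  D[0][0] = 0.0;
  for (int m = 1; m <= k; m++) {
    for (int j = m; j <= n; j++) {
      double best = R_PosInf;
      int bi = m - 1;
      for (int i = m - 1; i < j; i++) {
        if (!R_finite(D[m - 1][i])) continue;
        double c = D[m - 1][i] + seg_cost(S1, S2, i, j);
        if (c < best - 1e-12) {
          best = c;
          bi = i;
        }
      }
      D[m][j] = best;
      B[m][j] = bi;
    }
  }
  std::vector<int> starts(k);
  int j = n;
  for (int m = k; m >= 1; m--) {
    starts[m - 1] = B[m][j] + 1;
    j = B[m][j];
  }
  return wrap(starts);
}
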