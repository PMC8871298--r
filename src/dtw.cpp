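#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping dissimilarity between two numeric series.
// Convention: step set {(1,0),(0,1),(1,1)}, local cost |a-b|, total cost is
// the unnormalized sum along the optimal monotone alignment path. An optional
// Sakoe-Chiba band constrains |i-j| <= band (band < 0 means unconstrained).
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector x, NumericVector y, int band) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (band >= 0 && band < std::abs(n - m))
    stop("band narrower than length difference");
  const double inf = std::numeric_limits<double>::infinity();
  // rolling two-row DP over the (n+1) x (m+1) cost table
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(x[i - 1] - y[j - 1]);
      double best = prev[j - 1];            // diagonal
      if (prev[j] < best) best = prev[j];   // insertion
      if (cur[j - 1] < best) best = cur[j - 1]; // deletion
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All pairwise DTW dissimilarities between rows of a matrix, returned as a
// condensed vector in the same order as stats::dist (column-major lower
// triangle).
// [[Rcpp::export(name = ".dtw_pdist")]]
NumericVector dtw_pdist(NumericMatrix x, int band) {
  const int n = x.nrow();
  NumericVector out((double)n * (n - 1) / 2);
  int k = 0;
  for (int i = 0; i < n - 1; ++i) {
    NumericVector xi = x(i, _);
    for (int j = i + 1; j < n; ++j) {
      out[k++] = dtw_cost(xi, x(j, _), band);
    }
  }
  return out;
}
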