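#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact minimization of  sum_k SSE(segment_k) + beta * (#segments - 1)
// by PELT (pruned exact linear time). The SSE cost is subadditive, so
// pruning with K = 0 preserves exactness; the returned partition attains
// the global minimum of the penalized cost.
//
// Returns 1-based end indices of the segments (last element is n).
// [[Rcpp::export(name = ".pelt_changepoints")]]
IntegerVector pelt_changepoints(NumericVector y, double beta) {
  const int n = y.size();
  if (n == 0) return IntegerVector(0);

  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1]  = cs[i]  + y[i];
    cs2[i + 1] = cs2[i] + y[i] * y[i];
  }

  std::vector<double> F(n + 1);
  std::vector<int> last(n + 1, 0);
  F[0] = -beta;
  // G[s] = F[s] - cs2[s]: the s-dependent part of F[s] + SSE(s, t)
  std::vector<double> G(n + 1);
  G[0] = F[0] - cs2[0];
  std::vector<int> cand{0};
  std::vector<double> val;

  const double* pcs = cs.data();
  for (int t = 1; t <= n; ++t) {
    const double A = cs[t], B = cs2[t];
    const size_t k = cand.size();
    val.resize(k);
    double best = R_PosInf;
    int bs = 0;
    for (size_t i = 0; i < k; ++i) {
      const int s = cand[i];
      const double d = A - pcs[s];
      const double v = G[s] + B - d * d / (t - s) + beta;
      val[i] = v;
      if (v < best) { best = v; bs = s; }
    }
    F[t] = best;
    last[t] = bs;
    G[t] = best - B;
    // keep s with F[s] + SSE(s,t) <= F[t], i.e. val - beta <= F[t]
    size_t w = 0;
    for (size_t i = 0; i < k; ++i)
      if (val[i] - beta <= best) cand[w++] = cand[i];
    cand.resize(w);
    cand.push_back(t);
  }

  std::vector<int> ends;
  for (int t = n; t > 0; t = last[t]) ends.push_back(t);
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
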