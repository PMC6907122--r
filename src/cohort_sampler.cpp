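#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequential conditional sampler for per-patient disease sets.
//
// Diseases are visited in a fresh random order for each patient; disease d is
// drawn Bernoulli(baseline[d] * f) where the factor f is the largest boost
// whose condition the already-sampled set satisfies:
//   * level boosts: groups(d, l) > 0 and another sampled disease shares that
//     group id at level l  -> boosts[l]
//   * hub coupling: hub diseases are boosted once any disease is present,
//     and every disease is boosted once a hub is present -> hub_boost
// Probabilities are clamped at 0.99; clamp events are counted.
// Uses R's RNG, so determinism is inherited from set.seed().
// [[Rcpp::export]]
List sample_cohort_cpp(int n_patients, NumericVector baseline,
                       IntegerMatrix groups, NumericVector boosts,
                       LogicalVector hub, double hub_boost) {
  const int D = baseline.size();
  const int L = groups.ncol();
  int n_groups = 0;
  for (int d = 0; d < D; ++d)
    for (int l = 0; l < L; ++l)
      if (groups(d, l) > n_groups) n_groups = groups(d, l);

  std::vector<int> order(D);
  std::vector<int> cnt((size_t)(n_groups + 1) * (L > 0 ? L : 1), 0);
  List out(n_patients);
  double clamped = 0;

  for (int p = 0; p < n_patients; ++p) {
    for (int d = 0; d < D; ++d) order[d] = d;
    for (int d = D - 1; d > 0; --d) {
      int k = (int)(unif_rand() * (d + 1));
      if (k > d) k = d;
      std::swap(order[d], order[k]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    int n_sampled = 0, n_hub = 0;
    std::vector<int> picked;

    for (int t = 0; t < D; ++t) {
      const int d = order[t];
      double f = 1.0;
      for (int l = 0; l < L; ++l) {
        int g = groups(d, l);
        if (g > 0 && cnt[(size_t)g * L + l] > 0 && boosts[l] > f) f = boosts[l];
      }
      if (hub_boost > 1.0) {
        if (hub[d]) {
          if (n_sampled > 0 && hub_boost > f) f = hub_boost;
        } else if (n_hub > 0 && hub_boost > f) {
          f = hub_boost;
        }
      }
      double pr = baseline[d] * f;
      if (pr > 0.99) { pr = 0.99; clamped += 1; }
      if (unif_rand() < pr) {
        picked.push_back(d + 1);
        ++n_sampled;
        if (hub[d]) ++n_hub;
        for (int l = 0; l < L; ++l) {
          int g = groups(d, l);
          if (g > 0) ++cnt[(size_t)g * L + l];
        }
      }
    }
    out[p] = IntegerVector(picked.begin(), picked.end());
  }
  return List::create(_["diseases"] = out, _["n_clamped"] = clamped);
}
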