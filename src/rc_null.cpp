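#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted sampling without replacement of n indices from N, written into
// out. Two equivalent routes:
//  * sparse draws (2n <= N): Walker alias sampling with replacement, keeping
//    first occurrences until n distinct taxa are collected. Conditional on
//    the current set, the next new taxon is j with probability
//    w_j / (1 - W_drawn), i.e. exactly successive weighted sampling.
//  * dense draws: Efraimidis-Spirakis exponential keys (the n smallest
//    Exp(1)/w_i), which avoids the rejection blow-up as n approaches N.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  int N;
  explicit AliasTable(const NumericVector& w) : prob(w.size()), alias(w.size()),
                                                N(w.size()) {
    double total = 0;
    for (int i = 0; i < N; ++i) total += w[i];
    std::vector<double> scaled(N);
    std::vector<int> small, large;
    for (int i = 0; i < N; ++i) {
      scaled[i] = w[i] / total * N;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] -= 1.0 - scaled[s];
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    for (int s : small) { prob[s] = 1.0; alias[s] = s; }
    for (int l : large) { prob[l] = 1.0; alias[l] = l; }
  }
  inline int draw() const {
    double u = R::unif_rand() * N;
    int j = (int)u;
    if (j >= N) j = N - 1;
    return (u - j) < prob[j] ? j : alias[j];
  }
};

static void draw_wor(const NumericVector& w, const AliasTable& alias,
                     int n, std::vector<int>& out,
                     std::vector<int>& stamp, int tick,
                     std::vector<double>& key, std::vector<int>& idx) {
  const int N = w.size();
  out.clear();
  if (2 * n <= N) {
    while ((int)out.size() < n) {
      int j = alias.draw();
      if (stamp[j] != tick) { stamp[j] = tick; out.push_back(j); }
    }
  } else {
    for (int i = 0; i < N; ++i) { key[i] = R::exp_rand() / w[i]; idx[i] = i; }
    if (n < N)
      std::nth_element(idx.begin(), idx.begin() + n, idx.end(),
                       [&](int a, int b) { return key[a] < key[b]; });
    for (int i = 0; i < n; ++i) { stamp[idx[i]] = tick; out.push_back(idx[i]); }
  }
}

// Monte-Carlo null distribution of the shared-taxa count between two
// communities assembled at sizes n_a and n_b from a weighted regional pool
// by sampling without replacement. Uses R's RNG, so results are reproducible
// under set.seed(). Returns c(#null < shared_obs, #null == shared_obs).
// [[Rcpp::export]]
IntegerVector rc_null_counts(NumericVector w, int n_a, int n_b,
                             int shared_obs, int iterations) {
  const int N = w.size();
  if (n_a < 1 || n_b < 1) stop("community sizes must be at least 1");
  if (n_a > N || n_b > N) stop("community size exceeds pool size");
  if (iterations < 1) stop("iterations must be at least 1");
  for (int i = 0; i < N; ++i)
    if (!(w[i] > 0)) stop("pool weights must be strictly positive");

  AliasTable alias(w);
  std::vector<int> stamp(N, -1), draw_a, draw_b, idx(N);
  std::vector<double> key(N);
  std::vector<char> in_a(N, 0);
  draw_a.reserve(n_a); draw_b.reserve(n_b);

  int below = 0, equal = 0;
  for (int it = 0; it < iterations; ++it) {
    draw_wor(w, alias, n_a, draw_a, stamp, 2 * it, key, idx);
    for (int j : draw_a) in_a[j] = 1;
    draw_wor(w, alias, n_b, draw_b, stamp, 2 * it + 1, key, idx);
    int shared = 0;
    for (int j : draw_b) shared += in_a[j];
    for (int j : draw_a) in_a[j] = 0;
    if (shared < shared_obs) ++below;
    else if (shared == shared_obs) ++equal;
  }
  return IntegerVector::create(below, equal);
}
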