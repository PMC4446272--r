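#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Running-sum enrichment statistics from hit positions only.
//
// w holds |score|^p for every gene in ranked order. Between hits the running
// sum decreases linearly, so its maximum can only occur at a hit and its
// minimum only just before a hit or at the walk's end; evaluating those
// candidates gives the exact extrema in O(k) instead of O(N).
static void es_from_sorted_pos(const NumericVector& w,
                               const std::vector<int>& pos, // 0-based, sorted
                               double& es, double& posdev, double& negdev) {
  const int N = w.size();
  const int k = static_cast<int>(pos.size());
  double NR = 0.0;
  for (int i = 0; i < k; ++i) NR += w[pos[i]];
  const double miss = 1.0 / static_cast<double>(N - k);
  double cum = 0.0, mx = 0.0, mn = 0.0;
  for (int i = 0; i < k; ++i) {
    const double drop = static_cast<double>(pos[i] - i) * miss;
    const double before = cum - drop; // value at the miss preceding hit i
    if (before < mn) mn = before;
    cum += (NR > 0.0) ? w[pos[i]] / NR : 1.0 / static_cast<double>(k);
    const double at = cum - drop;
    if (at > mx) mx = at;
  }
  // walk ends at zero: cum == 1 and total miss decrement == 1
  posdev = mx;
  negdev = mn;
  es = (mx >= -mn) ? mx : mn;
}

//' @noRd
// [[Rcpp::export]]
NumericVector es_hits_cpp(NumericVector w, IntegerVector hit_pos1) {
  std::vector<int> pos(hit_pos1.size());
  for (int i = 0; i < hit_pos1.size(); ++i) pos[i] = hit_pos1[i] - 1;
  std::sort(pos.begin(), pos.end());
  double es, pd, nd;
  es_from_sorted_pos(w, pos, es, pd, nd);
  return NumericVector::create(es, pd, nd);
}

// B random gene sets of size k drawn without replacement from the ranked
// universe; returns per-draw (es, posdev, negdev). Uses R's RNG so results
// are reproducible under set.seed().
//' @noRd
// [[Rcpp::export]]
NumericMatrix perm_es_cpp(NumericVector w, int k, int B) {
  const int N = w.size();
  if (k <= 0 || k >= N) stop("set size must be in [1, N-1]");
  NumericMatrix out(B, 3);
  std::vector<int> idx(N);
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<int> pos(k);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < k; ++i) { // partial Fisher-Yates
      int j = i + static_cast<int>(unif_rand() * static_cast<double>(N - i));
      if (j >= N) j = N - 1;
      std::swap(idx[i], idx[j]);
      pos[i] = idx[i];
    }
    std::sort(pos.begin(), pos.end());
    double es, pd, nd;
    es_from_sorted_pos(w, pos, es, pd, nd);
    out(b, 0) = es;
    out(b, 1) = pd;
    out(b, 2) = nd;
  }
  return out;
}
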