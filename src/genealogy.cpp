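#include <Rcpp.h>
using namespace Rcpp;

// Subtree cell counts over the clone genealogy. Clone ids are 1-based and
// topologically ordered (every parent id is smaller than its children), so a
// single reverse sweep accumulates each clone's subtree: the number of live
// cells carrying the mutations that originated in that clone.
// [[Rcpp::export(name = ".subtree_carriers")]]
NumericVector subtree_carriers(IntegerVector parent, IntegerVector ids,
                               NumericVector counts) {
  R_xlen_t n = parent.size();
  NumericVector carriers(n);
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    carriers[ids[i] - 1] += counts[i];
  }
  for (R_xlen_t i = n - 1; i >= 1; --i) {
    int p = parent[i];
    if (p >= 1) carriers[p - 1] += carriers[i];
  }
  return carriers;
}

// Root-to-node path sums of a per-clone quantity g (forward sweep; parents
// precede children).
// [[Rcpp::export(name = ".path_sums")]]
NumericVector path_sums(IntegerVector parent, NumericVector g) {
  R_xlen_t n = parent.size();
  NumericVector out(n);
  if (n == 0) return out;
  out[0] = g[0];
  for (R_xlen_t i = 1; i < n; ++i) {
    int p = parent[i];
    out[i] = g[i] + (p >= 1 ? out[p - 1] : 0.0);
  }
  return out;
}
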