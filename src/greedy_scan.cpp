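#include <Rcpp.h>
using namespace Rcpp;

// Sequential scan used by the independence-constrained sampler: records are
// visited in the (already randomized) order given; a record is accepted iff
// neither its family nor its area has been claimed by an earlier acceptance.
// The result is maximal with respect to the scan order: every skipped record
// clashed with an accepted one, and the clash persists to the end of the scan.
//
// [[Rcpp::export]]
IntegerVector greedy_independent_scan(IntegerVector order,
                                      IntegerVector family,
                                      IntegerVector area,
                                      int n_family,
                                      int n_area) {
  std::vector<bool> fam_seen(n_family + 1, false);
  std::vector<bool> area_seen(n_area + 1, false);
  std::vector<int> keep;
  keep.reserve(order.size());
  for (int k = 0; k < order.size(); ++k) {
    int i = order[k] - 1;  // 1-based from R
    int f = family[i];
    int a = area[i];
    if (!fam_seen[f] && !area_seen[a]) {
      fam_seen[f] = true;
      area_seen[a] = true;
      keep.push_back(i + 1);
    }
  }
  return wrap(keep);
}
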