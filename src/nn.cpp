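#include <Rcpp.h>
#include <limits>

using namespace Rcpp;

// Brute-force nearest neighbour from each query row to the reference rows.
// Returns 1-based indices and squared distances. Reference clouds here are a
// few thousand points, where the O(nq * nr) scan is fast and allocation-free.
// [[Rcpp::export(name = ".nnBrute")]]
List nnBrute(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bestj = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bestj = j; }
    }
    idx[i] = bestj + 1;
    d2[i] = best;
  }
  return List::create(_["index"] = idx, _["dist2"] = d2);
}
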