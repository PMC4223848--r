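#include <Rcpp.h>
using namespace Rcpp;

// First-order nearest neighbors with tie handling.
//
// For each point, scan all other points, track the minimum distance and
// every point whose distance lies within `tol` of it.  Points whose
// minimum distance exceeds `max_radius` are excluded.  Returns flat
// pair vectors (1-based positions) plus the per-pair tied distance.
//
// O(n^2) but in compiled code; exact, so it doubles as the reference
// the R-level API is tested against for large n.
// [[Rcpp::export]]
List nn_pairs_euclidean(NumericVector x, NumericVector y,
                        double max_radius, double tol) {
  const int n = x.size();
  std::vector<int> index_pos, neighbor_pos;
  std::vector<double> dist;
  std::vector<int> ties;
  ties.reserve(8);

  for (int i = 0; i < n; ++i) {
    double dmin = R_PosInf;
    ties.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i];
      const double dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d < dmin - tol) {
        dmin = d;
        ties.clear();
        ties.push_back(j);
      } else if (d <= dmin + tol) {
        if (d < dmin) dmin = d;
        ties.push_back(j);
      }
    }
    if (dmin <= max_radius) {
      // re-filter: early candidates may no longer be within tol of the
      // final minimum
      for (size_t t = 0; t < ties.size(); ++t) {
        const int j = ties[t];
        const double dx = x[j] - x[i];
        const double dy = y[j] - y[i];
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d <= dmin + tol) {
          index_pos.push_back(i + 1);
          neighbor_pos.push_back(j + 1);
          dist.push_back(d);
        }
      }
    }
  }
  return List::create(_["index_pos"] = wrap(index_pos),
                      _["neighbor_pos"] = wrap(neighbor_pos),
                      _["distance"] = wrap(dist));
}
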