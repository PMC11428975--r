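#include <Rcpp.h>
using namespace Rcpp;

// Nearest target point for every moving point (Euclidean, brute force).
// Ties break deterministically to the lowest target index because only a
// strictly smaller squared distance replaces the incumbent.
// [[Rcpp::export(name = ".nn_bruteforce")]]
List nn_bruteforce(NumericMatrix moving, NumericMatrix target) {
  const int n = moving.nrow(), m = target.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    const double px = moving(i, 0), py = moving(i, 1), pz = moving(i, 2);
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = target(j, 0) - px;
      const double dy = target(j, 1) - py;
      const double dz = target(j, 2) - pz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
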