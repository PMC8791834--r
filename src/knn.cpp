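#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Distance from each point to its n-th nearest neighbour among the same
// points (self excluded). Brute force with partial selection; slides hold a
// few thousand cells, so O(m^2) is fine.
// [[Rcpp::export(name = ".knn_dist_n_cpp")]]
NumericVector knn_dist_n_cpp(NumericMatrix pts, int n_neighbour) {
  const int m = pts.nrow();
  if (m <= n_neighbour) stop("need more than n_neighbour points");
  NumericVector out(m);
  std::vector<double> d2(m - 1);
  for (int i = 0; i < m; ++i) {
    int k = 0;
    const double xi = pts(i, 0), yi = pts(i, 1);
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi;
      d2[k++] = dx * dx + dy * dy;
    }
    std::nth_element(d2.begin(), d2.begin() + (n_neighbour - 1), d2.end());
    out[i] = std::sqrt(d2[n_neighbour - 1]);
  }
  return out;
}
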