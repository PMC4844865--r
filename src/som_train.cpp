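#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen updates for a scalar-weight SOM. The caller supplies the
// sample order and the per-step learning-rate and radius schedules, so this
// loop is fully deterministic. Ties in the BMU search go to the lowest node
// index (strict < comparison while scanning ascending indices).
// [[Rcpp::export]]
NumericVector som_train_cpp(NumericVector w, NumericMatrix d2,
                            NumericVector x, NumericVector lr,
                            NumericVector radius) {
  int n_nodes = w.size();
  int n_steps = x.size();
  NumericVector wt = clone(w);
  for (int t = 0; t < n_steps; ++t) {
    double xv = x[t];
    int bmu = 0;
    double best = std::abs(wt[0] - xv);
    for (int k = 1; k < n_nodes; ++k) {
      double d = std::abs(wt[k] - xv);
      if (d < best) { best = d; bmu = k; }
    }
    double a = lr[t];
    double s2 = 2.0 * radius[t] * radius[t];
    if (s2 <= 0) {
      wt[bmu] += a * (xv - wt[bmu]);
      continue;
    }
    for (int k = 0; k < n_nodes; ++k) {
      double h = std::exp(-d2(k, bmu) / s2);
      wt[k] += a * h * (xv - wt[k]);
    }
  }
  return wt;
}
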