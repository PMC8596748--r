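#include <Rcpp.h>
using namespace Rcpp;

// One epoch of hinge-loss SGD with L2 penalty on the weights (intercept
// unpenalized), inverse-scaling "optimal" step size eta_t = 1/(alpha*(t0+t)).
// `order` is a 0-based visiting order for this epoch; `t` is the global
// update counter carried across epochs. Returns the updated state and the
// summed hinge loss of the epoch (evaluated before each update, as the
// running training loss used for the stopping rule).
// [[Rcpp::export]]
List sgd_epoch(const NumericMatrix& X, const IntegerVector& y,
               NumericVector w_in, double b, double t,
               double alpha, double t0, const IntegerVector& order) {
  const int n = order.size();
  const int p = X.ncol();
  NumericVector w = clone(w_in);
  double sumloss = 0.0;
  for (int k = 0; k < n; ++k) {
    const int i = order[k];
    const double eta = 1.0 / (alpha * (t0 + t));
    double score = b;
    for (int j = 0; j < p; ++j) score += w[j] * X(i, j);
    const double yi = (double) y[i];      // +1 / -1
    const double z = yi * score;
    if (z < 1.0) sumloss += 1.0 - z;
    const double decay = 1.0 - eta * alpha;
    for (int j = 0; j < p; ++j) w[j] *= decay;
    if (z < 1.0) {
      for (int j = 0; j < p; ++j) w[j] += eta * yi * X(i, j);
      b += eta * yi;
    }
    t += 1.0;
  }
  return List::create(_["w"] = w, _["b"] = b, _["t"] = t,
                      _["sumloss"] = sumloss);
}
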