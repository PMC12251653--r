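// Fused Adam update for one parameter tensor. The first/second moment
// buffers are owned by the optimizer and updated in place; the parameter
// is returned as a fresh vector so R copy-on-write semantics are
// preserved for the network object.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".adam_tensor")]]
NumericVector adam_tensor(NumericVector p, NumericVector g,
                          NumericVector m, NumericVector v, int t,
                          double lr, double b1, double b2, double eps) {
  const int n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam: size mismatch");
  NumericVector out(no_init(n));
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  for (int i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    out[i] = p[i] - lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}
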