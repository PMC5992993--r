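#include <Rcpp.h>
using namespace Rcpp;

// Inverse-CDF sampling of a first-order Markov chain: the initial state is
// drawn from pi, every subsequent state from the current state's row of T,
// one fresh U[0,1] draw per step. Uses R's RNG so set.seed() governs.
// Labels are 0-based.
// [[Rcpp::export]]
IntegerVector markov_chain_cpp(NumericVector pi, NumericMatrix T, int n) {
  const int ns = pi.size();
  if (T.nrow() != ns || T.ncol() != ns)
    stop("pi and T have inconsistent dimensions");
  if (n < 1) stop("n must be positive");

  // cumulative partitions of the unit interval
  NumericVector cpi(ns);
  double acc = 0.0;
  for (int i = 0; i < ns; ++i) { acc += pi[i]; cpi[i] = acc; }
  cpi[ns - 1] = 1.0;
  NumericMatrix cT(ns, ns);
  for (int i = 0; i < ns; ++i) {
    acc = 0.0;
    for (int j = 0; j < ns; ++j) { acc += T(i, j); cT(i, j) = acc; }
    cT(i, ns - 1) = 1.0;
  }

  IntegerVector out(n);
  double r = unif_rand();
  int s = 0;
  while (s < ns - 1 && r >= cpi[s]) ++s;
  out[0] = s;
  for (int t = 1; t < n; ++t) {
    r = unif_rand();
    int j = 0;
    while (j < ns - 1 && r >= cT(s, j)) ++j;
    out[t] = j;
    s = j;
  }
  return out;
}
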