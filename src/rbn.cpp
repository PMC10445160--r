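#include <Rcpp.h>
using namespace Rcpp;

// Synchronous update of a fixed in-degree random Boolean network.
//
// The network state x in {0,1}^N evolves as
//   x_i(t) = theta( w_in[i] * u(t) + sum_k w[k,i] * x[pre[k,i]](t-1) )
// with theta the strict Heaviside step, theta(0) = 0.
//
// pre:   K x N integer matrix, 1-based presynaptic indices per neuron
// w:     K x N numeric matrix, weights aligned with pre
// w_in:  length-N input weight vector (zero outside the input half)
// state0: length-N initial state in {0,1}
// input: length-T drive series u(t); all zeros for free runs
// record_idx: 1-based neuron indices whose states are recorded each step
//             (empty vector -> no state history, only activity counts)
//
// Returns: counts  - integer vector, number of active neurons after each step
//          history - T x length(record_idx) integer matrix (if requested)
//          final   - final state vector
// [[Rcpp::export(name = ".rbn_simulate")]]
List rbn_simulate(IntegerMatrix pre, NumericMatrix w, NumericVector w_in,
                  IntegerVector state0, NumericVector input,
                  IntegerVector record_idx) {
  const int K = pre.nrow();
  const int N = pre.ncol();
  const int T = input.size();
  if (w.nrow() != K || w.ncol() != N)
    stop("weight matrix dimensions do not match the presynaptic table");
  if (state0.size() != N)
    stop("initial state length does not match the number of neurons");
  if (w_in.size() != N)
    stop("input weight vector length does not match the number of neurons");

  std::vector<int> x(state0.begin(), state0.end());
  std::vector<int> xn(N);
  IntegerVector counts(T);
  const int R = record_idx.size();
  IntegerMatrix hist(R > 0 ? T : 0, R);

  const int *pp = INTEGER(pre);
  const double *wp = REAL(w);
  const double *wi = REAL(w_in);

  for (int t = 0; t < T; ++t) {
    const double u = input[t];
    int c = 0;
    for (int i = 0; i < N; ++i) {
      double s = wi[i] * u;
      const int off = i * K;
      for (int k = 0; k < K; ++k)
        s += wp[off + k] * x[pp[off + k] - 1];
      const int v = (s > 0.0) ? 1 : 0;  // theta(0) = 0, strictly
      xn[i] = v;
      c += v;
    }
    x.swap(xn);
    counts[t] = c;
    for (int r = 0; r < R; ++r)
      hist(t, r) = x[record_idx[r] - 1];
  }

  return List::create(_["counts"] = counts,
                      _["history"] = hist,
                      _["final"] = IntegerVector(x.begin(), x.end()));
}
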