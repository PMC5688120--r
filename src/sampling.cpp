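#include <Rcpp.h>
using namespace Rcpp;

// Draw the next state from a row of cumulative transition probabilities.
// Linear scan: state counts here are O(10^2), so this beats binary search
// overhead in practice.
static inline int draw_next(const NumericMatrix &cumT, int state, double u) {
  int n = cumT.ncol();
  for (int j = 0; j < n; ++j) {
    if (u <= cumT(state, j)) return j;
  }
  return n - 1; // guard against rounding at the upper edge
}

// [[Rcpp::export]]
IntegerVector cpp_sample_chain(NumericMatrix cumT, int n_steps, int start) {
  IntegerVector out(n_steps);
  int s = start;
  out[0] = s;
  for (int t = 1; t < n_steps; ++t) {
    s = draw_next(cumT, s, unif_rand());
    out[t] = s;
  }
  return out + 1; // 1-based state labels for R
}

// First-hit step counts for a batch of independent walkers.  Walkers start
// at `starts` (0-based) and stop on entering a sink state; the number of
// lag steps taken is recorded.  max_steps caps runaway walks (returned as
// NA) so a mis-specified sink cannot hang the caller.
// [[Rcpp::export]]
NumericVector cpp_first_hit_steps(NumericMatrix cumT, IntegerVector starts,
                                  LogicalVector is_sink, double max_steps) {
  int n_runs = starts.size();
  NumericVector out(n_runs);
  for (int r = 0; r < n_runs; ++r) {
    int s = starts[r];
    double steps = 0.0;
    while (!is_sink[s]) {
      s = draw_next(cumT, s, unif_rand());
      steps += 1.0;
      if (steps >= max_steps) {
        steps = NA_REAL;
        break;
      }
    }
    out[r] = steps;
  }
  return out;
}
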