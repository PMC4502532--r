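#include <Rcpp.h>
using namespace Rcpp;

// One full Monte Carlo sweep of pairwise Fermi imitation: n elementary steps,
// each drawing an ordered pair (i, j) uniformly (j != i), computing both
// players' current-group payoffs phi = (1 - c) + (r/s) * group_pot, and
// letting j adopt i's strategy with probability 1 / (1 + exp((phi_j -
// phi_i)/K)). Group pots are kept incrementally so each step is O(1).
//
// Exactly three uniforms are consumed per elementary step (pair draw twice,
// adoption once, the latter even when i and j already agree) so the pure-R
// mirror used in tests consumes the RNG stream identically.
// [[Rcpp::export]]
IntegerVector imitation_sweep_cpp(IntegerVector strategies,
                                  IntegerVector groups,
                                  double r, int s, double K) {
  const int n = strategies.size();
  IntegerVector strat = clone(strategies);
  const int k = n / s;
  std::vector<double> pot(k, 0.0);
  for (int a = 0; a < n; ++a) pot[groups[a] - 1] += strat[a];
  const double rs = r / (double) s;
  for (int step = 0; step < n; ++step) {
    double u1 = unif_rand();
    double u2 = unif_rand();
    double u3 = unif_rand();
    int i = (int) (u1 * n);       if (i > n - 1) i = n - 1;
    int j = (int) (u2 * (n - 1)); if (j > n - 2) j = n - 2;
    if (j >= i) ++j;
    double phi_i = (1.0 - strat[i]) + rs * pot[groups[i] - 1];
    double phi_j = (1.0 - strat[j]) + rs * pot[groups[j] - 1];
    double w = 1.0 / (1.0 + std::exp((phi_j - phi_i) / K));
    if (u3 < w && strat[j] != strat[i]) {
      pot[groups[j] - 1] += strat[i] - strat[j];
      strat[j] = strat[i];
    }
  }
  return strat;
}
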