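#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven (Gillespie) simulation of the two-state telegraph
// promoter over a labeling window [0, t_label]. State: promoter ON/OFF and
// the number of labeled transcripts. Synthesis (rate k_syn) only while ON;
// first-order degradation (rate k_deg per molecule). The labeled counter
// starts at 0 at labeling onset; the promoter starts from its stationary
// Bernoulli(k_on / (k_on + k_off)) law. Uses R's RNG so set.seed() applies.
// [[Rcpp::export]]
IntegerVector telegraph_ssa(int n_cells, double k_on, double k_off,
                            double k_syn, double k_deg, double t_label) {
  IntegerVector out(n_cells);
  double denom = k_on + k_off;
  double p_on = denom > 0 ? k_on / denom : 0.5;
  for (int c = 0; c < n_cells; ++c) {
    bool on = unif_rand() < p_on;
    int m = 0;
    double t = 0.0;
    for (;;) {
      double r_switch = on ? k_off : k_on;
      double r_birth = on ? k_syn : 0.0;
      double r_death = k_deg * m;
      double total = r_switch + r_birth + r_death;
      if (total <= 0.0) break;
      t += exp_rand() / total;
      if (t > t_label) break;
      double u = unif_rand() * total;
      if (u < r_switch) {
        on = !on;
      } else if (u < r_switch + r_birth) {
        ++m;
      } else {
        --m;
      }
    }
    out[c] = m;
  }
  return out;
}
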