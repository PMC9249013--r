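#include <Rcpp.h>
using namespace Rcpp;

// Sequential point-process event loop for one fiber.
//
// Candidate events are pulse arrivals; t_us holds the evaluation time of
// each candidate (end of the cathodic phase) and ieff the leaky-integrated
// effective current there, in the same unit as theta. For each candidate a
// jittered spike time is proposed; candidates landing inside the absolute
// refractory period of the previous spike are discarded, later ones face a
// relatively refractory threshold elevated by a factor 1 + exp(-dt/tau).
// Firing probability is the Gaussian integral Phi((ieff - theta_eff) /
// (rs * theta)). Uses R's RNG, so results are reproducible via set.seed().
//
// Candidates whose upper-bound firing probability (at the floor threshold
// theta) is below ~1e-12 are skipped without consuming RNG draws.
// [[Rcpp::export]]
NumericVector sim_fiber_cpp(NumericVector t_us, NumericVector ieff,
                            double theta, double rs, double jitter_sd,
                            double abs_ref, double rel_tau) {
  const int n = t_us.size();
  const double sd = rs * theta;
  std::vector<double> spikes;
  double last = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if ((ieff[i] - theta) / sd < -7.0) continue;
    double prop = t_us[i];
    if (jitter_sd > 0) prop += R::rnorm(0.0, jitter_sd);
    if (prop <= last + abs_ref) continue;  // absolute refractory
    double theta_eff = theta;
    if (R_FINITE(last))
      theta_eff = theta * (1.0 + std::exp(-(prop - last - abs_ref) / rel_tau));
    double p = R::pnorm((ieff[i] - theta_eff) / sd, 0.0, 1.0, 1, 0);
    if (R::unif_rand() < p) {
      spikes.push_back(prop);
      last = prop;
    }
  }
  return wrap(spikes);
}
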