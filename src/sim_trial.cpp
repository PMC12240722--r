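#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One sequential-sampling trial: at each step, draw a noisy value sample of
// the attended item, update its conjugate Gaussian posterior with the
// assumed (possibly biased) precision, then assess the value of additional
// computation over a geometric menu of candidate horizons. Sampling stops
// when no candidate horizon has positive net value; reaching the deadline
// without such a stop aborts the trial. RNG goes through R's stream so
// set.seed() governs reproducibility and R reference code can match draws.
//
// Mirrors the R primitives update_posterior() / assess_voc() exactly; the
// test suite cross-checks the two paths under a shared seed.

// [[Rcpp::export]]
List sim_trial_cpp(NumericVector true_value, NumericVector tau_samp,
                   NumericVector tau_upd, double mu_prior, double lambda_prior,
                   double cost, double dt_ms, int cap,
                   IntegerVector attended, NumericVector shares) {
  if (true_value.size() != 2 || tau_samp.size() != 2 || tau_upd.size() != 2 ||
      shares.size() != 2 || attended.size() < cap)
    stop("sim_trial_cpp: malformed inputs");
  for (int i = 0; i < 2; i++)
    if (tau_samp[i] <= 0 || tau_upd[i] <= 0)
      stop("invalid parameter: non-positive precision");

  double n[2] = {0.0, 0.0}, xbar[2] = {0.0, 0.0};
  double mu[2] = {mu_prior, mu_prior};
  double lam[2] = {lambda_prior, lambda_prior};
  double sd_samp[2] = {1.0 / std::sqrt(tau_samp[0]), 1.0 / std::sqrt(tau_samp[1])};
  const int short_i = (shares[0] <= shares[1]) ? 0 : 1;
  const int long_i = 1 - short_i;
  const double cost_per_sample = cost * dt_ms / 1000.0;

  bool stopped = false;
  int t = 0;
  while (t < cap) {
    t++;
    int i = attended[t - 1] - 1;
    double x = true_value[i] + norm_rand() * sd_samp[i];
    n[i] += 1.0;
    xbar[i] += (x - xbar[i]) / n[i];
    lam[i] = lambda_prior + n[i] * tau_upd[i];
    mu[i] = mu_prior + (n[i] * tau_upd[i] / lam[i]) * (xbar[i] - mu_prior);

    int remaining = cap - t;
    if (remaining < 1) break;  // deadline reached while still wanting to sample

    bool cont = false;
    double mumax = std::max(mu[0], mu[1]);
    for (long h = 1;; h *= 2) {
      long hh = h;
      bool last = false;
      if (h >= remaining) { hh = remaining; last = true; }
      long hsplit[2];
      hsplit[short_i] = (long) std::lround(hh * shares[short_i]);
      hsplit[long_i] = hh - hsplit[short_i];
      double v0 = 1.0 / lam[0] - 1.0 / (lam[0] + hsplit[0] * tau_upd[0]);
      double v1 = 1.0 / lam[1] - 1.0 / (lam[1] + hsplit[1] * tau_upd[1]);
      double theta = std::sqrt(std::max(v0, 0.0) + std::max(v1, 0.0));
      double gain = 0.0;
      if (theta > 0.0) {
        // E[max] - max(mu) in cancellation-free form
        double ad = std::fabs(mu[0] - mu[1]);
        double z = ad / theta;
        gain = std::max(theta * R::dnorm(z, 0.0, 1.0, 0) -
                        ad * R::pnorm(-z, 0.0, 1.0, 1, 0), 0.0);
      }
      // continue on non-negative net value; see assess_voc()
      if (gain - cost_per_sample * hh >= 0.0) { cont = true; break; }
      if (last) break;
    }
    if (!cont) { stopped = true; break; }
  }

  int choice = NA_INTEGER;
  if (stopped) {
    if (mu[0] > mu[1]) choice = 1;
    else if (mu[1] > mu[0]) choice = 2;
    else choice = (unif_rand() < 0.5) ? 1 : 2;
  }
  return List::create(
    _["choice"] = choice,
    _["n_samples"] = t,
    _["aborted"] = !stopped,
    _["n"] = NumericVector::create(n[0], n[1]),
    _["sample_mean"] = NumericVector::create(xbar[0], xbar[1]),
    _["mu"] = NumericVector::create(mu[0], mu[1]),
    _["lam"] = NumericVector::create(lam[0], lam[1]));
}
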