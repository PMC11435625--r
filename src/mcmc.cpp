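#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the substrate-depletion measurement
// model.  Parameters: indicator z_bio ~ Bern(p_clear), z_abio ~ Bern(p_abio);
// rates k_bio, k_abio ~ U(0, k_max); log response factor ~ N(rf_logmean,
// rf_logsd); noise sd (log-response scale) ~ half-Normal(0, noise_scale).
// Observation likelihood: log response ~ N(mu, noise_sd) with
//   mu = logRF + log C_test - (z_bio k_bio + z_abio k_abio) t   (cells)
//   mu = logRF + log C_test - z_abio k_abio t                   (controls)
//   mu = logRF + log nominal_conc                               (calibration)
// Left-censored rows contribute Phi((logRF + log LOQ - mu)/sd).
// Indicators are drawn from their full conditionals; when an indicator is 0
// its rate is refreshed from the prior (pseudo-prior) so chains mix across
// model configurations.  Random-walk steps adapt during burn-in only.

struct ModelData {
  NumericVector t;        // minutes
  NumericVector logresp;  // log response (ignored where censored)
  IntegerVector type;     // 0 cells, 1 control, 2 calibration
  LogicalVector cens;     // left-censored at LOQ
  NumericVector logcal;   // log nominal conc for calibration rows
  double log_ctest;
  double log_loq;
};

static double loglik(const ModelData& d, int z_bio, int z_abio,
                     double k_bio, double k_abio, double logrf, double nsd) {
  const int n = d.t.size();
  if (n == 0) return 0.0;
  double kc = z_bio * k_bio + z_abio * k_abio;
  double ka = z_abio * k_abio;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double mu;
    if (d.type[i] == 2)       mu = logrf + d.logcal[i];
    else if (d.type[i] == 1)  mu = logrf + d.log_ctest - ka * d.t[i];
    else                      mu = logrf + d.log_ctest - kc * d.t[i];
    if (d.cens[i]) {
      ll += R::pnorm(logrf + d.log_loq, mu, nsd, 1, 1);
    } else {
      ll += R::dnorm(d.logresp[i], mu, nsd, 1);
    }
  }
  return ll;
}

// [[Rcpp::export]]
NumericMatrix mcmc_depletion_cpp(NumericVector t, NumericVector logresp,
                                 IntegerVector type, LogicalVector censored,
                                 NumericVector logcal,
                                 double log_ctest, double log_loq,
                                 double p_clear, double p_abio, double k_max,
                                 double rf_logmean, double rf_logsd,
                                 double noise_scale,
                                 int n_iter, int n_burn,
                                 double k_bio0, double k_abio0,
                                 int z_bio0, int z_abio0,
                                 double logrf0, double nsd0) {
  ModelData d{t, logresp, type, censored, logcal, log_ctest, log_loq};
  RNGScope scope;

  double k_bio = k_bio0, k_abio = k_abio0, logrf = logrf0;
  double lognsd = std::log(nsd0);
  int z_bio = z_bio0, z_abio = z_abio0;

  // step sizes and burn-in acceptance bookkeeping for the four RW updates
  double step[4] = {k_max / 10.0, k_max / 10.0, 0.2, 0.3};
  int acc[4] = {0, 0, 0, 0}, tries[4] = {0, 0, 0, 0};
  const int adapt_every = 50;

  double nsd = std::exp(lognsd);
  double cur_ll = loglik(d, z_bio, z_abio, k_bio, k_abio, logrf, nsd);

  NumericMatrix out(n_iter, 6);
  colnames(out) = CharacterVector::create("z_bio", "z_abio", "k_bio",
                                          "k_abio", "rf", "noise_sd");

  for (int it = 0; it < n_iter; ++it) {
    // -- k_bio ------------------------------------------------------------
    if (z_bio == 1) {
      double prop = k_bio + R::norm_rand() * step[0];
      ++tries[0];
      if (prop > 0.0 && prop < k_max) {
        double ll = loglik(d, z_bio, z_abio, prop, k_abio, logrf, nsd);
        if (std::log(R::unif_rand()) < ll - cur_ll) {
          k_bio = prop; cur_ll = ll; ++acc[0];
        }
      }
    } else {
      k_bio = R::unif_rand() * k_max;  // pseudo-prior refresh
    }
    // -- k_abio -----------------------------------------------------------
    if (z_abio == 1) {
      double prop = k_abio + R::norm_rand() * step[1];
      ++tries[1];
      if (prop > 0.0 && prop < k_max) {
        double ll = loglik(d, z_bio, z_abio, k_bio, prop, logrf, nsd);
        if (std::log(R::unif_rand()) < ll - cur_ll) {
          k_abio = prop; cur_ll = ll; ++acc[1];
        }
      }
    } else {
      k_abio = R::unif_rand() * k_max;
    }
    // -- z_bio (full conditional) ----------------------------------------
    {
      double l1 = loglik(d, 1, z_abio, k_bio, k_abio, logrf, nsd);
      double l0 = loglik(d, 0, z_abio, k_bio, k_abio, logrf, nsd);
      double m = std::max(l1, l0);
      double w1 = p_clear * std::exp(l1 - m);
      double w0 = (1.0 - p_clear) * std::exp(l0 - m);
      z_bio = (R::unif_rand() < w1 / (w1 + w0)) ? 1 : 0;
      cur_ll = z_bio ? l1 : l0;
    }
    // -- z_abio -----------------------------------------------------------
    {
      double l1 = loglik(d, z_bio, 1, k_bio, k_abio, logrf, nsd);
      double l0 = loglik(d, z_bio, 0, k_bio, k_abio, logrf, nsd);
      double m = std::max(l1, l0);
      double w1 = p_abio * std::exp(l1 - m);
      double w0 = (1.0 - p_abio) * std::exp(l0 - m);
      z_abio = (R::unif_rand() < w1 / (w1 + w0)) ? 1 : 0;
      cur_ll = z_abio ? l1 : l0;
    }
    // -- log RF -----------------------------------------------------------
    {
      double prop = logrf + R::norm_rand() * step[2];
      ++tries[2];
      double ll = loglik(d, z_bio, z_abio, k_bio, k_abio, prop, nsd);
      double lr = ll - cur_ll
        + R::dnorm(prop, rf_logmean, rf_logsd, 1)
        - R::dnorm(logrf, rf_logmean, rf_logsd, 1);
      if (std::log(R::unif_rand()) < lr) {
        logrf = prop; cur_ll = ll; ++acc[2];
      }
    }
    // -- log noise sd (half-normal prior on sd, Jacobian for log scale) ---
    {
      double prop = lognsd + R::norm_rand() * step[3];
      ++tries[3];
      double nsd_p = std::exp(prop);
      double ll = loglik(d, z_bio, z_abio, k_bio, k_abio, logrf, nsd_p);
      double lr = ll - cur_ll
        + R::dnorm(nsd_p, 0.0, noise_scale, 1) + prop
        - (R::dnorm(nsd, 0.0, noise_scale, 1) + lognsd);
      if (std::log(R::unif_rand()) < lr) {
        lognsd = prop; nsd = nsd_p; cur_ll = ll; ++acc[3];
      }
    }
    // -- adapt during burn-in only ---------------------------------------
    if (it < n_burn && (it + 1) % adapt_every == 0) {
      for (int j = 0; j < 4; ++j) {
        if (tries[j] > 0) {
          double rate = (double)acc[j] / tries[j];
          step[j] *= std::exp(rate - 0.44);
          step[j] = std::min(std::max(step[j], 1e-8), 10.0);
        }
        acc[j] = 0; tries[j] = 0;
      }
    }
    out(it, 0) = z_bio;
    out(it, 1) = z_abio;
    out(it, 2) = k_bio;
    out(it, 3) = k_abio;
    out(it, 4) = std::exp(logrf);
    out(it, 5) = nsd;
  }
  return out;
}
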