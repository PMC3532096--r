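#include <Rcpp.h>
using namespace Rcpp;

// BayesC-pi Gibbs sampler.
//
// Model: y = mu + sum_j x_j beta_j delta_j + e, e ~ N(0, sigma2_e I);
// beta_j | delta_j = 1 ~ N(0, sigma2_beta) (common slab variance);
// Pr(delta_j = 1) = 1 - pi, pi ~ Uniform(0,1);
// sigma2_beta, sigma2_e ~ scaled inverse chi-square (nu, S2).
//
// Each locus's (delta_j, beta_j) pair is drawn jointly from its conditional
// Bernoulli-normal; the running residual r = y - mu - X beta is updated in
// place. Uses R's RNG, so results are reproducible under set.seed().

static double sample_scaled_inv_chisq(double nu, double ss) {
  // draw from (ss) / chisq_nu, with ss = nu*S2 + accumulated squares
  return ss / R::rchisq(nu);
}

// [[Rcpp::export(name = ".bayescpi_gibbs")]]
List bayescpi_gibbs(NumericVector y, NumericMatrix M,
                    int iterations, int burn_in,
                    double pi_start, bool update_pi,
                    double nu_beta, double scale_beta, bool update_sigma_beta,
                    double nu_e, double scale_e,
                    int thin, bool shuffle) {
  const int n = y.size();
  const int m = M.ncol();
  if (burn_in >= iterations)
    stop("iterations must exceed burn_in");

  std::vector<double> xtx(m), beta(m, 0.0);
  std::vector<int> delta(m, 0), order(m);
  std::vector<bool> skip(m, false);
  for (int j = 0; j < m; ++j) {
    const double *x = &M(0, j);
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) { s += x[i]; ss += x[i] * x[i]; }
    xtx[j] = ss;
    // constant column (zero dosage variance): never fit
    skip[j] = (ss - s * s / n) < 1e-12;
    order[j] = j;
  }

  double mu = mean(y);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  double pi = pi_start;
  double sigma2_beta = scale_beta;   // started at the prior scale
  double sigma2_e = scale_e;

  const int kept = iterations - burn_in;
  NumericVector beta_sum(m), incl_sum(m);
  const int ntrace = (kept + thin - 1) / thin;
  NumericVector pi_trace(ntrace), s2b_trace(ntrace), s2e_trace(ntrace);
  double pi_sum = 0, s2b_sum = 0, s2e_sum = 0, varprop_sum = 0, k_sum = 0;
  int trace_at = 0;

  for (int it = 0; it < iterations; ++it) {
    // intercept
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar = rbar / n + mu;
    double mu_new = R::rnorm(rbar, std::sqrt(sigma2_e / n));
    double dmu = mu - mu_new;
    for (int i = 0; i < n; ++i) r[i] += dmu;
    mu = mu_new;

    if (shuffle) {  // Fisher-Yates on the update order
      for (int j = m - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        std::swap(order[j], order[k]);
      }
    }

    int k_in = 0;
    double ssb = 0.0;
    const double log_prior_odds = std::log((1.0 - pi) / pi);
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      if (skip[j]) continue;
      const double *x = &M(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += x[i] * r[i];
      const double bold = delta[j] ? beta[j] : 0.0;
      if (delta[j]) rhs += xtx[j] * bold;   // residual without locus j
      const double v1 = xtx[j] + sigma2_e / sigma2_beta;
      const double log_bf = 0.5 * rhs * rhs / (sigma2_e * v1)
        - 0.5 * std::log1p(xtx[j] * sigma2_beta / sigma2_e);
      const double lo = log_prior_odds + log_bf;
      const double p1 = 1.0 / (1.0 + std::exp(-lo));
      double bnew = 0.0;
      int dnew = (unif_rand() < p1) ? 1 : 0;
      if (dnew) {
        bnew = R::rnorm(rhs / v1, std::sqrt(sigma2_e / v1));
        ++k_in;
        ssb += bnew * bnew;
      }
      const double db = bold - bnew;
      if (db != 0.0) for (int i = 0; i < n; ++i) r[i] += x[i] * db;
      beta[j] = bnew;
      delta[j] = dnew;
    }

    if (update_pi) pi = R::rbeta(m - k_in + 1.0, k_in + 1.0);

    if (update_sigma_beta)
      sigma2_beta = sample_scaled_inv_chisq(nu_beta + k_in,
                                            nu_beta * scale_beta + ssb);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += r[i] * r[i];
    sigma2_e = sample_scaled_inv_chisq(nu_e + n, nu_e * scale_e + sse);

    if (it >= burn_in) {
      for (int j = 0; j < m; ++j) {
        if (delta[j]) { beta_sum[j] += beta[j]; incl_sum[j] += 1.0; }
      }
      pi_sum += pi; s2b_sum += sigma2_beta; s2e_sum += sigma2_e;
      k_sum += k_in;
      // genetic values g = y - mu - r; proportion of variance explained
      double gs = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double gi = y[i] - mu - r[i];
        gs += gi; gss += gi * gi;
      }
      double vg = (gss - gs * gs / n) / (n - 1);
      varprop_sum += vg / (vg + sigma2_e);
      int rel = it - burn_in;
      if (rel % thin == 0) {
        pi_trace[trace_at] = pi;
        s2b_trace[trace_at] = sigma2_beta;
        s2e_trace[trace_at] = sigma2_e;
        ++trace_at;
      }
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["effect_mean"] = beta_sum / (double)kept,
    _["inclusion_prob"] = incl_sum / (double)kept,
    _["pi_mean"] = pi_sum / kept,
    _["pi_trace"] = pi_trace,
    _["sigma2_beta_mean"] = s2b_sum / kept,
    _["sigma2_beta_trace"] = s2b_trace,
    _["sigma2_e_mean"] = s2e_sum / kept,
    _["sigma2_e_trace"] = s2e_trace,
    _["varprop_mean"] = varprop_sum / kept,
    _["k_mean"] = k_sum / kept,
    _["skipped"] = wrap(std::vector<int>(skip.begin(), skip.end())),
    _["final_mu"] = mu,
    _["final_beta"] = [&] {  // beta * delta at the last sweep
      NumericVector fb(m);
      for (int j = 0; j < m; ++j) fb[j] = delta[j] ? beta[j] : 0.0;
      return fb;
    }(),
    _["final_residual"] = wrap(r));
}
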