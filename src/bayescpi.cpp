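#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for BayesC-pi whole-genome regression:
//   y = mu + W beta + e,
//   beta_m = 0 with prob 1 - pi, ~ N(0, sigma_beta^2) with prob pi,
//   sigma_beta^2 and sigma_e^2 scaled-inverse-chi-square,
//   pi ~ Beta(pi_a, pi_b) (optionally fixed).
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
List bayescpi_gibbs(const NumericMatrix& W, const NumericVector& y,
                    int n_iter, int burn_in, int thin,
                    double nu_beta, double S_beta,
                    double nu_e, double S_e,
                    bool sample_pi, double pi_init,
                    double pi_a, double pi_b,
                    bool sample_var, double sb2_init, double se2_init) {
  const int n = W.nrow(), p = W.ncol();
  RNGScope scope;

  std::vector<double> wtw(p);
  for (int m = 0; m < p; ++m) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, m) * W(i, m);
    wtw[m] = s;
  }

  std::vector<double> beta(p, 0.0);
  std::vector<int> delta(p, 0);
  double mu = Rcpp::mean(y);
  std::vector<double> ycorr(n);
  for (int i = 0; i < n; ++i) ycorr[i] = y[i] - mu;

  double pi = pi_init;
  double sb2 = sample_var ? S_beta * nu_beta / std::max(nu_beta - 2.0, 0.5)
                          : sb2_init;
  double se2 = sample_var ? S_e * nu_e / std::max(nu_e - 2.0, 0.5) : se2_init;

  std::vector<double> beta_sum(p, 0.0), beta_sumsq(p, 0.0), incl_sum(p, 0.0);
  double pi_sum = 0, sb2_sum = 0, se2_sum = 0, mu_sum = 0;
  int n_samples = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept (conjugate normal given everything else)
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += ycorr[i];
    ybar /= n;
    double mu_shift = ybar + norm_rand() * std::sqrt(se2 / n);
    mu += mu_shift;
    for (int i = 0; i < n; ++i) ycorr[i] -= mu_shift;

    // SNP effects and inclusion indicators
    int k = 0;
    double ssb = 0.0;
    for (int m = 0; m < p; ++m) {
      double c = wtw[m];
      if (c <= 0.0) { beta[m] = 0.0; delta[m] = 0; continue; }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += W(i, m) * ycorr[i];
      rhs += c * beta[m];  // effect of SNP m removed from ycorr

      double prob1;
      if (pi >= 1.0) prob1 = 1.0;
      else if (pi <= 0.0) prob1 = 0.0;
      else {
        double v0 = c * se2;
        double v1 = c * se2 + c * c * sb2;
        double log_odds = std::log(pi / (1.0 - pi)) +
          0.5 * (std::log(v0 / v1) + rhs * rhs * (1.0 / v0 - 1.0 / v1));
        prob1 = 1.0 / (1.0 + std::exp(-log_odds));
      }
      int d_new = (unif_rand() < prob1) ? 1 : 0;
      double b_new = 0.0;
      if (d_new == 1) {
        double C = c + se2 / sb2;
        b_new = rhs / C + norm_rand() * std::sqrt(se2 / C);
        ++k;
        ssb += b_new * b_new;
      }
      double diff = beta[m] - b_new;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) ycorr[i] += W(i, m) * diff;
      beta[m] = b_new;
      delta[m] = d_new;
    }

    // common effect variance
    if (sample_var)
      sb2 = (ssb + nu_beta * S_beta) / R::rchisq(nu_beta + k);

    // pi
    if (sample_pi) pi = R::rbeta(pi_a + k, pi_b + (p - k));

    // residual variance
    if (sample_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += ycorr[i] * ycorr[i];
      se2 = (sse + nu_e * S_e) / R::rchisq(nu_e + n);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++n_samples;
      for (int m = 0; m < p; ++m) {
        beta_sum[m] += beta[m];
        beta_sumsq[m] += beta[m] * beta[m];
        incl_sum[m] += delta[m];
      }
      pi_sum += pi;
      sb2_sum += sb2;
      se2_sum += se2;
      mu_sum += mu;
    }
  }

  if (n_samples == 0) stop("no post-burn-in samples; check chain settings");
  NumericVector bmean(p), bsd(p), incl(p);
  for (int m = 0; m < p; ++m) {
    bmean[m] = beta_sum[m] / n_samples;
    double v = beta_sumsq[m] / n_samples - bmean[m] * bmean[m];
    bsd[m] = std::sqrt(std::max(v, 0.0));
    incl[m] = incl_sum[m] / n_samples;
  }
  return List::create(
    _["beta_mean"] = bmean, _["beta_sd"] = bsd,
    _["inclusion_prob"] = incl,
    _["pi_hat"] = pi_sum / n_samples,
    _["sigma_beta2"] = sb2_sum / n_samples,
    _["sigma_e2"] = se2_sum / n_samples,
    _["intercept"] = mu_sum / n_samples,
    _["n_samples"] = n_samples);
}
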