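#include <Rcpp.h>
using namespace Rcpp;

// BayesB Metropolis-within-Gibbs sampler.
//
// Model: y = 1*mu + Z u + e,  u_i ~ N(0, s2u_i),
//        s2u_i = 0 with prob Pi_u, else scaled-inv-chi2(nu_u, S2_u),
//        Pi_u ~ Beta(pi_a, pi_b), nu_u ~ Gamma(shape, scale),
//        S2_u ~ Gamma(shape, scale), s2e ~ scaled-inv-chi2(nu_e, S2_e).
//
// Per SNP the variance state (zero vs a fresh draw from its prior) is
// proposed with the effect integrated out of the likelihood, so the
// acceptance ratio only involves the scalar projection of the residual on
// that SNP; the effect is then drawn from its Gaussian full conditional.
// nu_u and S2_u move by adaptive random-walk Metropolis on the log scale;
// Pi_u and s2e use conjugate full conditionals. All randomness comes from
// the R RNG, so set.seed() upstream fixes the run exactly.

// log marginal likelihood contribution of one SNP with effect integrated out
static inline double loglik_var(double s, double a, double c, double s2e) {
  if (s <= 0.0) return 0.0;
  return -0.5 * std::log1p(c * s / s2e) +
         0.5 * a * a * s / (s2e * (s2e + c * s));
}

// log density of scaled-inverse-chi-squared(nu, S2) at s
static inline double log_sinvchi2(double s, double nu, double S2) {
  return 0.5 * nu * std::log(0.5 * nu * S2) - R::lgammafn(0.5 * nu) -
         (1.0 + 0.5 * nu) * std::log(s) - 0.5 * nu * S2 / s;
}

static inline double log_gamma_pdf(double x, double shape, double scale) {
  return (shape - 1.0) * std::log(x) - x / scale - R::lgammafn(shape) -
         shape * std::log(scale);
}

// [[Rcpp::export]]
List bayesb_gibbs(NumericMatrix Z, NumericVector y,
                  int n_iter, int burn_in, int thin,
                  double pi_a, double pi_b,
                  double nu_u_shape, double nu_u_scale,
                  double s2u_shape, double s2u_scale,
                  double nu_e, double S2_e,
                  bool include_all, double fixed_effect_var,
                  double fixed_resid_var, double fix_mu) {
  const int n = Z.nrow(), p = Z.ncol();
  const bool var_fixed = R_finite(fixed_effect_var);
  const bool s2e_fixed = R_finite(fixed_resid_var);
  const bool mu_fixed = R_finite(fix_mu);

  // column inner products
  std::vector<double> cj(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    cj[j] = s;
  }

  // state
  std::vector<double> u(p, 0.0), s2u(p, 0.0);
  double ybar = mean(y);
  double mu = mu_fixed ? fix_mu : ybar;
  double s2e = s2e_fixed ? fixed_resid_var : var(y) * 0.5;
  if (s2e <= 0) s2e = 1e-8;
  double pi_u = include_all ? 0.0 : pi_a / (pi_a + pi_b);
  double nu_u = nu_u_shape * nu_u_scale;   // prior means as starting values
  double S2_u = s2u_shape * s2u_scale;
  if (var_fixed) {
    for (int j = 0; j < p; ++j) s2u[j] = fixed_effect_var;
  }

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  // accumulators
  std::vector<double> u_sum(p, 0.0), u_sq(p, 0.0), incl(p, 0.0);
  double mu_sum = 0, pi_sum = 0, nu_sum = 0, s2u_sum = 0, s2e_sum = 0;
  int n_samples = (n_iter - burn_in) / thin;
  NumericVector tr_s2e(n_samples), tr_pi(n_samples), tr_nu(n_samples),
      tr_s2u(n_samples);
  int stored = 0;

  // adaptive RW steps for log(nu_u), log(S2_u)
  double step_nu = 0.3, step_s2 = 0.5;
  long acc_nu = 0, try_nu = 0, acc_s2 = 0, try_s2 = 0;
  long win_acc_nu = 0, win_try_nu = 0, win_acc_s2 = 0, win_try_s2 = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // intercept
    if (!mu_fixed) {
      double rm = 0.0;
      for (int i = 0; i < n; ++i) rm += r[i] + mu;
      rm /= n;
      double mu_new = rm + R::rnorm(0.0, std::sqrt(s2e / n));
      double d = mu - mu_new;
      for (int i = 0; i < n; ++i) r[i] += d;
      mu = mu_new;
    }

    // per-SNP joint update of (inclusion/variance, effect)
    for (int j = 0; j < p; ++j) {
      double a = cj[j] * u[j];
      for (int i = 0; i < n; ++i) a += Z(i, j) * r[i];

      if (!var_fixed) {
        double s_prop;
        if (!include_all && R::runif(0.0, 1.0) < pi_u) {
          s_prop = 0.0;
        } else {
          s_prop = nu_u * S2_u / R::rchisq(nu_u);
        }
        double log_ratio = loglik_var(s_prop, a, cj[j], s2e) -
                           loglik_var(s2u[j], a, cj[j], s2e);
        if (log_ratio >= 0.0 || R::runif(0.0, 1.0) < std::exp(log_ratio)) {
          s2u[j] = s_prop;
        }
      }

      double u_new = 0.0;
      if (s2u[j] > 0.0) {
        double prec = cj[j] / s2e + 1.0 / s2u[j];
        double mean_u = (a / s2e) / prec;
        u_new = mean_u + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      }
      double d = u[j] - u_new;
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] += Z(i, j) * d;
      }
      u[j] = u_new;
    }

    int m_in = 0;
    for (int j = 0; j < p; ++j) if (s2u[j] > 0.0) ++m_in;

    // Pi_u | inclusion counts (conjugate Beta)
    if (!include_all && !var_fixed) {
      pi_u = R::rbeta(pi_a + (p - m_in), pi_b + m_in);
    }

    // nu_u, S2_u | included variance states (random walk on log scale)
    if (!var_fixed) {
      double loglik_cur = 0.0;
      for (int j = 0; j < p; ++j)
        if (s2u[j] > 0.0) loglik_cur += log_sinvchi2(s2u[j], nu_u, S2_u);

      // nu_u
      {
        double nu_prop = nu_u * std::exp(step_nu * R::rnorm(0.0, 1.0));
        double ll_prop = 0.0;
        for (int j = 0; j < p; ++j)
          if (s2u[j] > 0.0) ll_prop += log_sinvchi2(s2u[j], nu_prop, S2_u);
        double lr = ll_prop + log_gamma_pdf(nu_prop, nu_u_shape, nu_u_scale) +
                    std::log(nu_prop) -
                    (loglik_cur + log_gamma_pdf(nu_u, nu_u_shape, nu_u_scale) +
                     std::log(nu_u));
        ++try_nu; ++win_try_nu;
        if (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr)) {
          nu_u = nu_prop;
          loglik_cur = ll_prop;
          ++acc_nu; ++win_acc_nu;
        }
      }
      // S2_u
      {
        double s2_prop = S2_u * std::exp(step_s2 * R::rnorm(0.0, 1.0));
        double ll_prop = 0.0;
        for (int j = 0; j < p; ++j)
          if (s2u[j] > 0.0) ll_prop += log_sinvchi2(s2u[j], nu_u, s2_prop);
        double lr = ll_prop + log_gamma_pdf(s2_prop, s2u_shape, s2u_scale) +
                    std::log(s2_prop) -
                    (loglik_cur + log_gamma_pdf(S2_u, s2u_shape, s2u_scale) +
                     std::log(S2_u));
        ++try_s2; ++win_try_s2;
        if (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr)) {
          S2_u = s2_prop;
          ++acc_s2; ++win_acc_s2;
        }
      }
      // step adaptation during burn-in, targeting ~30% acceptance
      if (iter <= burn_in && iter % 100 == 0) {
        if (win_try_nu > 0) {
          double ar = (double)win_acc_nu / win_try_nu;
          step_nu *= (ar > 0.4) ? 1.2 : (ar < 0.2 ? 0.8 : 1.0);
          win_acc_nu = win_try_nu = 0;
        }
        if (win_try_s2 > 0) {
          double ar = (double)win_acc_s2 / win_try_s2;
          step_s2 *= (ar > 0.4) ? 1.2 : (ar < 0.2 ? 0.8 : 1.0);
          win_acc_s2 = win_try_s2 = 0;
        }
        acc_nu = try_nu = acc_s2 = try_s2 = 0;  // count post-adaptation only
      }
    }

    // residual variance (conjugate scaled-inv-chi2)
    if (!s2e_fixed) {
      double rss = 0.0;
      for (int i = 0; i < n; ++i) rss += r[i] * r[i];
      s2e = (rss + nu_e * S2_e) / R::rchisq((double)n + nu_e);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        u_sum[j] += u[j];
        u_sq[j] += u[j] * u[j];
        if (s2u[j] > 0.0) incl[j] += 1.0;
      }
      mu_sum += mu; pi_sum += pi_u; nu_sum += nu_u;
      s2u_sum += S2_u; s2e_sum += s2e;
      tr_s2e[stored] = s2e; tr_pi[stored] = pi_u;
      tr_nu[stored] = nu_u; tr_s2u[stored] = S2_u;
      ++stored;
    }
    if (iter % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector u_mean(p), u_sd(p), incl_prob(p);
  for (int j = 0; j < p; ++j) {
    u_mean[j] = u_sum[j] / stored;
    double v = u_sq[j] / stored - u_mean[j] * u_mean[j];
    u_sd[j] = std::sqrt(std::max(v, 0.0));
    incl_prob[j] = incl[j] / stored;
  }

  return List::create(
      _["u_mean"] = u_mean, _["u_sd"] = u_sd, _["incl_prob"] = incl_prob,
      _["mu_mean"] = mu_sum / stored, _["pi_mean"] = pi_sum / stored,
      _["nu_u_mean"] = nu_sum / stored, _["s2u_mean"] = s2u_sum / stored,
      _["s2e_mean"] = s2e_sum / stored,
      _["acc_nu"] = try_nu > 0 ? (double)acc_nu / try_nu : 1.0,
      _["acc_s2"] = try_s2 > 0 ? (double)acc_s2 / try_s2 : 1.0,
      _["n_samples"] = stored,
      _["trace_s2e"] = tr_s2e, _["trace_pi"] = tr_pi,
      _["trace_nu"] = tr_nu, _["trace_s2u"] = tr_s2u);
}
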