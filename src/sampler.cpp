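#include <Rcpp.h>
using namespace Rcpp;

// Beta-binomial log pmf with the binomial coefficient precomputed once per clone.
static inline double bb_lpmf(double m, double N, double a, double b,
                             double lchoose_mN) {
  return lchoose_mN + R::lbeta(m + a, N - m + b) - R::lbeta(a, b);
}

static inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Conditional log-likelihood given hard clone assignments.
// r1 = rbar - d/2 (lower allele), r2 = rbar + d/2.
static double loglik_assigned(const NumericVector& m, const NumericVector& N,
                              const NumericVector& lch, const IntegerVector& c,
                              double rbar, double d, double s1, double s2) {
  const double mu1 = expit(rbar - d / 2.0), mu2 = expit(rbar + d / 2.0);
  const double a1 = s1 * mu1, b1 = s1 - a1;
  const double a2 = s2 * mu2, b2 = s2 - a2;
  double ll = 0.0;
  for (int j = 0; j < m.size(); ++j) {
    if (c[j] == 1) ll += bb_lpmf(m[j], N[j], a1, b1, lch[j]);
    else           ll += bb_lpmf(m[j], N[j], a2, b2, lch[j]);
  }
  return ll;
}

// One MCMC chain for the two-component beta-binomial mixture with a
// spike-and-slab prior on the allele difference d (point mass zero_mass at
// d = 0, gamma slab for d > 0).  Metropolis-within-Gibbs:
//   - Gibbs draw of clone indicators given parameters (fixed 0.5 mixing),
//   - random-walk Metropolis on rbar, log s1, log s2,
//   - spike/slab jump moves on (z, d) using the slab prior as proposal,
//     plus a log-scale random walk on d when z = 1,
//   - proposal scales adapted during burn-in only.
// Uses R's RNG, so reproducibility is controlled by set.seed() in R.
// [[Rcpp::export]]
List bbmix_chain_cpp(NumericVector m, NumericVector N,
                     double rbar_mean, double rbar_sd, double zero_mass,
                     double d_shape, double d_rate,
                     double s_shape, double s_rate,
                     int burn_in, int n_iter,
                     double init_rbar, double init_d,
                     double init_s1, double init_s2) {
  const int n = m.size();
  NumericVector lch(n);
  for (int j = 0; j < n; ++j) lch[j] = R::lchoose(N[j], m[j]);

  double rbar = init_rbar, d = init_d, s1 = init_s1, s2 = init_s2;
  int z = (d > 0.0) ? 1 : 0;
  if (zero_mass >= 1.0) { z = 0; d = 0.0; }
  IntegerVector c(n, 1);

  double step_rbar = 0.4, step_s1 = 0.6, step_s2 = 0.6, step_d = 0.4;
  int acc_rbar = 0, try_rbar = 0, acc_s1 = 0, try_s1 = 0,
      acc_s2 = 0, try_s2 = 0, acc_d = 0, try_d = 0;

  NumericMatrix draws(n_iter, 6);  // rbar, d, s1, s2, mu1, mu2
  NumericVector assign1(n, 0.0);
  double z_sum = 0.0;

  const int total = burn_in + n_iter;
  for (int it = 0; it < total; ++it) {
    // --- Gibbs update of clone indicators ---
    {
      const double mu1 = expit(rbar - d / 2.0), mu2 = expit(rbar + d / 2.0);
      const double a1 = s1 * mu1, b1 = s1 - a1;
      const double a2 = s2 * mu2, b2 = s2 - a2;
      for (int j = 0; j < n; ++j) {
        const double l1 = bb_lpmf(m[j], N[j], a1, b1, lch[j]);
        const double l2 = bb_lpmf(m[j], N[j], a2, b2, lch[j]);
        const double p1 = 1.0 / (1.0 + std::exp(l2 - l1));
        c[j] = (R::unif_rand() < p1) ? 1 : 2;
      }
    }

    // --- rbar: random-walk Metropolis ---
    {
      const double prop = rbar + R::norm_rand() * step_rbar;
      const double la =
        R::dnorm(prop, rbar_mean, rbar_sd, 1) -
        R::dnorm(rbar, rbar_mean, rbar_sd, 1) +
        loglik_assigned(m, N, lch, c, prop, d, s1, s2) -
        loglik_assigned(m, N, lch, c, rbar, d, s1, s2);
      ++try_rbar;
      if (std::log(R::unif_rand()) < la) { rbar = prop; ++acc_rbar; }
    }

    // --- s1, s2: random walk on the log scale (gamma prior + Jacobian) ---
    for (int which = 1; which <= 2; ++which) {
      double& s = (which == 1) ? s1 : s2;
      double& step = (which == 1) ? step_s1 : step_s2;
      int& acc = (which == 1) ? acc_s1 : acc_s2;
      int& tr = (which == 1) ? try_s1 : try_s2;
      const double cur = s;
      const double prop = cur * std::exp(R::norm_rand() * step);
      double la = s_shape * (std::log(prop) - std::log(cur)) -
                  s_rate * (prop - cur);
      s = prop;
      la += loglik_assigned(m, N, lch, c, rbar, d, s1, s2);
      s = cur;
      la -= loglik_assigned(m, N, lch, c, rbar, d, s1, s2);
      ++tr;
      if (std::log(R::unif_rand()) < la) { s = prop; ++acc; }
    }

    // --- (z, d): spike/slab jump or within-slab random walk ---
    if (zero_mass < 1.0) {
      if (R::unif_rand() < 0.5) {
        // Jump move with the slab prior as proposal: the gamma densities
        // cancel and only the likelihood ratio and the mass ratio remain.
        if (z == 0) {
          const double prop = R::rgamma(d_shape, 1.0 / d_rate);
          const double la =
            std::log(1.0 - zero_mass) - std::log(zero_mass) +
            loglik_assigned(m, N, lch, c, rbar, prop, s1, s2) -
            loglik_assigned(m, N, lch, c, rbar, 0.0, s1, s2);
          if (std::log(R::unif_rand()) < la) { z = 1; d = prop; }
        } else {
          double la = loglik_assigned(m, N, lch, c, rbar, 0.0, s1, s2) -
                      loglik_assigned(m, N, lch, c, rbar, d, s1, s2);
          la += (zero_mass > 0.0 ? std::log(zero_mass) : R_NegInf) -
                std::log(1.0 - zero_mass);
          if (std::log(R::unif_rand()) < la) { z = 0; d = 0.0; }
        }
      } else if (z == 1) {
        const double prop = d * std::exp(R::norm_rand() * step_d);
        // gamma log-density + log-scale Jacobian: shape*log(d) - rate*d
        const double la =
          d_shape * (std::log(prop) - std::log(d)) - d_rate * (prop - d) +
          loglik_assigned(m, N, lch, c, rbar, prop, s1, s2) -
          loglik_assigned(m, N, lch, c, rbar, d, s1, s2);
        ++try_d;
        if (std::log(R::unif_rand()) < la) { d = prop; ++acc_d; }
      }
    }

    // --- adapt proposal scales during burn-in only ---
    if (it < burn_in && (it + 1) % 50 == 0) {
      if (try_rbar > 0)
        step_rbar = std::min(5.0, std::max(0.01,
          step_rbar * std::exp((double)acc_rbar / try_rbar - 0.44)));
      if (try_s1 > 0)
        step_s1 = std::min(5.0, std::max(0.01,
          step_s1 * std::exp((double)acc_s1 / try_s1 - 0.44)));
      if (try_s2 > 0)
        step_s2 = std::min(5.0, std::max(0.01,
          step_s2 * std::exp((double)acc_s2 / try_s2 - 0.44)));
      if (try_d > 0)
        step_d = std::min(5.0, std::max(0.01,
          step_d * std::exp((double)acc_d / try_d - 0.44)));
      acc_rbar = try_rbar = acc_s1 = try_s1 = 0;
      acc_s2 = try_s2 = acc_d = try_d = 0;
    }

    if (it >= burn_in) {
      const int k = it - burn_in;
      draws(k, 0) = rbar;
      draws(k, 1) = d;
      draws(k, 2) = s1;
      draws(k, 3) = s2;
      draws(k, 4) = expit(rbar - d / 2.0);
      draws(k, 5) = expit(rbar + d / 2.0);
      z_sum += z;
      for (int j = 0; j < n; ++j) if (c[j] == 1) assign1[j] += 1.0;
    }
  }

  for (int j = 0; j < n; ++j) assign1[j] /= n_iter;
  return List::create(_["draws"] = draws,
                      _["assign_p1"] = assign1,
                      _["p_z1"] = z_sum / n_iter);
}

// One MCMC chain for the mono-allelic model: a single beta-binomial with
// r ~ N(r_mean, r_sd), s ~ gamma(s_shape, rate = s_rate).
// [[Rcpp::export]]
List bbmono_chain_cpp(NumericVector m, NumericVector N,
                      double r_mean, double r_sd,
                      double s_shape, double s_rate,
                      int burn_in, int n_iter,
                      double init_r, double init_s) {
  const int n = m.size();
  NumericVector lch(n);
  for (int j = 0; j < n; ++j) lch[j] = R::lchoose(N[j], m[j]);

  double r = init_r, s = init_s;
  double step_r = 0.3, step_s = 0.5;
  int acc_r = 0, try_r = 0, acc_s = 0, try_s = 0;

  NumericMatrix draws(n_iter, 3);  // r, s, mu

  auto ll = [&](double rr, double ss) {
    const double mu = expit(rr);
    const double a = ss * mu, b = ss - a;
    double out = 0.0;
    for (int j = 0; j < n; ++j) out += bb_lpmf(m[j], N[j], a, b, lch[j]);
    return out;
  };

  const int total = burn_in + n_iter;
  for (int it = 0; it < total; ++it) {
    {
      const double prop = r + R::norm_rand() * step_r;
      const double la = R::dnorm(prop, r_mean, r_sd, 1) -
                        R::dnorm(r, r_mean, r_sd, 1) +
                        ll(prop, s) - ll(r, s);
      ++try_r;
      if (std::log(R::unif_rand()) < la) { r = prop; ++acc_r; }
    }
    {
      const double prop = s * std::exp(R::norm_rand() * step_s);
      const double la = s_shape * (std::log(prop) - std::log(s)) -
                        s_rate * (prop - s) + ll(r, prop) - ll(r, s);
      ++try_s;
      if (std::log(R::unif_rand()) < la) { s = prop; ++acc_s; }
    }
    if (it < burn_in && (it + 1) % 50 == 0) {
      if (try_r > 0)
        step_r = std::min(5.0, std::max(0.01,
          step_r * std::exp((double)acc_r / try_r - 0.44)));
      if (try_s > 0)
        step_s = std::min(5.0, std::max(0.01,
          step_s * std::exp((double)acc_s / try_s - 0.44)));
      acc_r = try_r = acc_s = try_s = 0;
    }
    if (it >= burn_in) {
      const int k = it - burn_in;
      draws(k, 0) = r;
      draws(k, 1) = s;
      draws(k, 2) = expit(r);
    }
  }
  return List::create(_["draws"] = draws);
}
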