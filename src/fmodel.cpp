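// Metropolis-within-Gibbs sampler for the hierarchical Bayesian F-model on
// dominant marker data.
//
// Data: per locus i and population j, the band-absence count m_ij out of
// n_ij individuals, with absence probability (1 - p_ij)^2 (dominant
// phenotype under Hardy-Weinberg).
// Model: p_ij ~ Beta(theta_ij * pi_i, theta_ij * (1 - pi_i)),
//        theta_ij = (1 - F_ij) / F_ij,
//        logit(F_ij) = alpha_i * delta_i + beta_j,
//        pi_i ~ U(0,1), alpha_i ~ N(0, alpha_sd), beta_j ~ N(beta_mean,
//        beta_sd), delta_i Bernoulli with prior odds `prior_odds` against
//        selection.
// The selection indicator delta_i is flipped by a Gibbs step in a
// Carlin-Chib composite space: while delta_i = 0, alpha_i is refreshed from
// a pseudo-prior fitted to pilot-run samples, and the flip odds weigh the
// real prior against that pseudo-prior. Pilot runs adapt all random-walk
// scales towards acceptance rates in [0.25, 0.45].

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double x) {
  return std::min(std::max(x, 1e-6), 1.0 - 1e-6);
}
static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double logit(double p) { return std::log(p / (1.0 - p)); }

// binomial log-likelihood of absence count m of n given presence allele
// frequency p (constants dropped)
static inline double ll_bin(int m, int n, double p) {
  double q2 = (1.0 - p) * (1.0 - p);
  q2 = std::min(std::max(q2, 1e-12), 1.0 - 1e-12);
  return m * std::log(q2) + (n - m) * std::log1p(-q2);
}

// log Beta(p; theta*pi, theta*(1-pi)) density
static inline double ldbeta_f(double p, double fst, double pi,
                              double lp, double l1p) {
  double f = std::min(std::max(fst, 1e-5), 1.0 - 1e-5);
  double th = (1.0 - f) / f;
  double a = th * pi, b = th * (1.0 - pi);
  return (a - 1.0) * lp + (b - 1.0) * l1p - R::lbeta(a, b);
}

struct Scales {
  std::vector<double> p, panc, alpha;
  std::vector<double> beta;
};

// [[Rcpp::export]]
List fmodel_mcmc(IntegerMatrix m_abs, IntegerMatrix n_obs,
                 int pilot_runs, int pilot_iter,
                 int iter, int burnin, int thin,
                 double prior_odds, double alpha_sd,
                 double beta_mean, double beta_sd,
                 bool fix_alpha) {
  const int L = m_abs.nrow(), K = m_abs.ncol();
  const double lprior1 = -std::log1p(prior_odds);           // log P(delta=1)
  const double lprior0 = std::log(prior_odds) - std::log1p(prior_odds);

  NumericMatrix p(L, K);
  NumericMatrix lp(L, K), l1p(L, K);
  std::vector<double> panc(L), alpha(L, 0.0), beta(K, logit(0.05));
  std::vector<int> delta(L, 0);
  std::vector<double> pp_mu(L, 0.0), pp_sd(L, 1.0);        // pseudo-priors

  // initialize p_ij and pi_i from the raw absence fractions
  for (int i = 0; i < L; ++i) {
    double tot_m = 0, tot_n = 0;
    for (int j = 0; j < K; ++j) {
      double n = n_obs(i, j);
      double q = clamp01(std::sqrt((m_abs(i, j) + 0.5) / (n + 1.0)));
      p(i, j) = clamp01(1.0 - q);
      lp(i, j) = std::log(p(i, j));
      l1p(i, j) = std::log1p(-p(i, j));
      tot_m += m_abs(i, j);
      tot_n += n;
    }
    panc[i] = clamp01(1.0 - std::sqrt((tot_m + 0.5) / (tot_n + 1.0)));
  }

  Scales sc;
  sc.p.assign(L, 0.8);
  sc.panc.assign(L, 0.5);
  sc.alpha.assign(L, 0.6);
  sc.beta.assign(K, 0.15);

  std::vector<long> acc_p(L, 0), try_p(L, 0), acc_pa(L, 0), try_pa(L, 0),
      acc_al(L, 0), try_al(L, 0), acc_be(K, 0), try_be(K, 0);

  double cur_f;  // scratch

  auto fst_of = [&](int i, int j) {
    return invlogit((fix_alpha ? 0.0 : alpha[i] * delta[i]) + beta[j]);
  };

  auto sweep = [&](bool pilot) {
    // 1. population frequencies p_ij (random walk on the logit scale)
    for (int i = 0; i < L; ++i) {
      for (int j = 0; j < K; ++j) {
        double cur = p(i, j);
        double prop = invlogit(logit(cur) + sc.p[i] * R::norm_rand());
        prop = clamp01(prop);
        double f = fst_of(i, j);
        double ff = std::min(std::max(f, 1e-5), 1.0 - 1e-5);
        double th = (1.0 - ff) / ff;
        double a = th * panc[i], b = th * (1.0 - panc[i]);
        double lpn = std::log(prop), l1pn = std::log1p(-prop);
        double lr = ll_bin(m_abs(i, j), n_obs(i, j), prop) -
                    ll_bin(m_abs(i, j), n_obs(i, j), cur) +
                    (a - 1.0) * (lpn - lp(i, j)) +
                    (b - 1.0) * (l1pn - l1p(i, j)) +
                    lpn + l1pn - lp(i, j) - l1p(i, j);  // Jacobian
        ++try_p[i];
        if (std::log(R::unif_rand()) < lr) {
          p(i, j) = prop;
          lp(i, j) = lpn;
          l1p(i, j) = l1pn;
          ++acc_p[i];
        }
      }
    }
    // 2. ancestral frequencies pi_i
    for (int i = 0; i < L; ++i) {
      double cur = panc[i];
      double prop = clamp01(invlogit(logit(cur) + sc.panc[i] * R::norm_rand()));
      double lr = std::log(prop) + std::log1p(-prop) -
                  std::log(cur) - std::log1p(-cur);  // Jacobian (flat prior)
      for (int j = 0; j < K; ++j) {
        cur_f = fst_of(i, j);
        lr += ldbeta_f(p(i, j), cur_f, prop, lp(i, j), l1p(i, j)) -
              ldbeta_f(p(i, j), cur_f, cur, lp(i, j), l1p(i, j));
      }
      ++try_pa[i];
      if (std::log(R::unif_rand()) < lr) {
        panc[i] = prop;
        ++acc_pa[i];
      }
    }
    if (!fix_alpha) {
      // 3. locus effects alpha_i
      for (int i = 0; i < L; ++i) {
        bool active = pilot || delta[i] == 1;
        if (active) {
          double cur = alpha[i];
          double prop = cur + sc.alpha[i] * R::norm_rand();
          double lr = R::dnorm(prop, 0.0, alpha_sd, 1) -
                      R::dnorm(cur, 0.0, alpha_sd, 1);
          for (int j = 0; j < K; ++j) {
            lr += ldbeta_f(p(i, j), invlogit(prop + beta[j]), panc[i],
                           lp(i, j), l1p(i, j)) -
                  ldbeta_f(p(i, j), invlogit(cur + beta[j]), panc[i],
                           lp(i, j), l1p(i, j));
          }
          ++try_al[i];
          if (std::log(R::unif_rand()) < lr) {
            alpha[i] = prop;
            ++acc_al[i];
          }
        } else {
          // delta = 0: refresh alpha from its pseudo-prior
          alpha[i] = pp_mu[i] + pp_sd[i] * R::norm_rand();
        }
      }
      // 4. selection indicators delta_i (Gibbs flip)
      if (!pilot) {
        for (int i = 0; i < L; ++i) {
          double lo = lprior1 - lprior0 +
                      R::dnorm(alpha[i], 0.0, alpha_sd, 1) -
                      R::dnorm(alpha[i], pp_mu[i], pp_sd[i], 1);
          for (int j = 0; j < K; ++j) {
            lo += ldbeta_f(p(i, j), invlogit(alpha[i] + beta[j]), panc[i],
                           lp(i, j), l1p(i, j)) -
                  ldbeta_f(p(i, j), invlogit(beta[j]), panc[i],
                           lp(i, j), l1p(i, j));
          }
          delta[i] = (R::unif_rand() < invlogit(lo)) ? 1 : 0;
        }
      }
    }
    // 5. population effects beta_j
    for (int j = 0; j < K; ++j) {
      double cur = beta[j];
      double prop = cur + sc.beta[j] * R::norm_rand();
      double lr = R::dnorm(prop, beta_mean, beta_sd, 1) -
                  R::dnorm(cur, beta_mean, beta_sd, 1);
      for (int i = 0; i < L; ++i) {
        double ad = fix_alpha ? 0.0 : alpha[i] * delta[i];
        lr += ldbeta_f(p(i, j), invlogit(ad + prop), panc[i],
                       lp(i, j), l1p(i, j)) -
              ldbeta_f(p(i, j), invlogit(ad + cur), panc[i],
                       lp(i, j), l1p(i, j));
      }
      ++try_be[j];
      if (std::log(R::unif_rand()) < lr) {
        beta[j] = prop;
        ++acc_be[j];
      }
    }
  };

  // ---- pilot runs: adapt scales, fit pseudo-priors (delta held at 1) ----
  if (!fix_alpha) for (int i = 0; i < L; ++i) delta[i] = 1;
  std::vector<double> al_sum(L, 0.0), al_sq(L, 0.0);
  long al_n = 0;
  for (int r = 0; r < pilot_runs; ++r) {
    std::fill(acc_p.begin(), acc_p.end(), 0);
    std::fill(try_p.begin(), try_p.end(), 0);
    std::fill(acc_pa.begin(), acc_pa.end(), 0);
    std::fill(try_pa.begin(), try_pa.end(), 0);
    std::fill(acc_al.begin(), acc_al.end(), 0);
    std::fill(try_al.begin(), try_al.end(), 0);
    std::fill(acc_be.begin(), acc_be.end(), 0);
    std::fill(try_be.begin(), try_be.end(), 0);
    for (int t = 0; t < pilot_iter; ++t) {
      sweep(true);
      if (r >= pilot_runs / 2) {
        for (int i = 0; i < L; ++i) {
          al_sum[i] += alpha[i];
          al_sq[i] += alpha[i] * alpha[i];
        }
        ++al_n;
      }
    }
    auto tune = [](double& s, long acc, long tries) {
      if (tries == 0) return;
      double r = double(acc) / tries;
      if (r > 0.45) s *= 1.3;
      else if (r < 0.25) s /= 1.3;
    };
    for (int i = 0; i < L; ++i) {
      tune(sc.p[i], acc_p[i], try_p[i]);
      tune(sc.panc[i], acc_pa[i], try_pa[i]);
      tune(sc.alpha[i], acc_al[i], try_al[i]);
    }
    for (int j = 0; j < K; ++j) tune(sc.beta[j], acc_be[j], try_be[j]);
  }
  if (!fix_alpha) {
    for (int i = 0; i < L; ++i) {
      if (al_n > 1) {
        double mu = al_sum[i] / al_n;
        double v = al_sq[i] / al_n - mu * mu;
        pp_mu[i] = mu;
        pp_sd[i] = std::max(std::sqrt(std::max(v, 0.0)), 0.1);
      }
    }
    for (int i = 0; i < L; ++i) delta[i] = 0;
  }

  // ---- main run ----
  std::fill(acc_p.begin(), acc_p.end(), 0);
  std::fill(try_p.begin(), try_p.end(), 0);
  std::fill(acc_pa.begin(), acc_pa.end(), 0);
  std::fill(try_pa.begin(), try_pa.end(), 0);
  std::fill(acc_al.begin(), acc_al.end(), 0);
  std::fill(try_al.begin(), try_al.end(), 0);
  std::fill(acc_be.begin(), acc_be.end(), 0);
  std::fill(try_be.begin(), try_be.end(), 0);

  std::vector<double> sum_delta(L, 0.0), sum_alpha(L, 0.0),
      sum_fstl(L, 0.0), sum_beta(K, 0.0), sum_fstp(K, 0.0);
  long n_samples = 0;
  for (int t = 0; t < iter; ++t) {
    sweep(false);
    if (t >= burnin && ((t - burnin) % thin == 0)) {
      ++n_samples;
      for (int i = 0; i < L; ++i) {
        sum_delta[i] += delta[i];
        sum_alpha[i] += alpha[i];
        double f = 0.0;
        for (int j = 0; j < K; ++j) f += fst_of(i, j);
        sum_fstl[i] += f / K;
      }
      for (int j = 0; j < K; ++j) {
        sum_beta[j] += beta[j];
        sum_fstp[j] += invlogit(beta[j]);
      }
    }
  }
  if (n_samples == 0) n_samples = 1;

  NumericVector pp(L), alpha_mean(L), fst_locus(L), beta_out(K), fst_pop(K);
  for (int i = 0; i < L; ++i) {
    pp[i] = sum_delta[i] / n_samples;
    alpha_mean[i] = sum_alpha[i] / n_samples;
    fst_locus[i] = sum_fstl[i] / n_samples;
  }
  for (int j = 0; j < K; ++j) {
    beta_out[j] = sum_beta[j] / n_samples;
    fst_pop[j] = sum_fstp[j] / n_samples;
  }
  auto rate = [](std::vector<long>& a, std::vector<long>& t) {
    double sa = 0, st = 0;
    for (size_t i = 0; i < a.size(); ++i) { sa += a[i]; st += t[i]; }
    return st > 0 ? sa / st : NA_REAL;
  };
  List acc = List::create(_["p"] = rate(acc_p, try_p),
                          _["p_anc"] = rate(acc_pa, try_pa),
                          _["alpha"] = rate(acc_al, try_al),
                          _["beta"] = rate(acc_be, try_be));
  return List::create(_["pp"] = pp, _["alpha_mean"] = alpha_mean,
                      _["fst_locus"] = fst_locus, _["beta_mean"] = beta_out,
                      _["fst_pop"] = fst_pop, _["acceptance"] = acc,
                      _["n_samples"] = (double)n_samples);
}
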