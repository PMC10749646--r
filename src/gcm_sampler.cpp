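#include <Rcpp.h>
using namespace Rcpp;

// General Condorcet Model sampler for one chain.
//
// Data: Y[i,k] in {0,1}, respondents i = 1..n, items k = 1..m.
// Effective accuracy D = theta*(1-delta) / (theta*(1-delta) + delta*(1-theta)),
// with the degenerate 0/0 case defined as D = 0.5.
// P(Y=1) = D + (1-D)*g when z = 1, and (1-D)*g when z = 0.
//
// Latent truths z are updated by exact Gibbs steps; theta, g, delta (and the
// hierarchical hyperparameters, when enabled) by adaptive random-walk
// Metropolis on the logit / log scale, adapting toward 0.44 acceptance during
// burn-in only. R's RNG is used throughout so chains are reproducible from
// set.seed() on the R side.

static inline double effective_accuracy(double th, double de) {
  double num = th * (1.0 - de);
  double den = num + de * (1.0 - th);
  if (den <= 0.0) return 0.5;
  return num / den;
}

static inline double cell_loglik(int y, double th, double g, double de, int z) {
  double D = effective_accuracy(th, de);
  double p = (z == 1) ? D + (1.0 - D) * g : (1.0 - D) * g;
  if (p < 1e-12) p = 1e-12;
  if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
  return (y == 1) ? std::log(p) : std::log1p(-p);
}

static inline double logit(double x) { return std::log(x / (1.0 - x)); }
static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log Beta(a, b) density of x, a = mu*kappa, b = (1-mu)*kappa
static inline double log_dbeta_mu_kappa(double x, double mu, double kappa) {
  return R::dbeta(x, mu * kappa, (1.0 - mu) * kappa, 1);
}

// [[Rcpp::export(name = ".gcm_chain_cpp")]]
List gcm_chain(IntegerMatrix Y, int samples, int burnin, int thin,
               bool hierarchical, double kappa_max) {
  const int n = Y.nrow();
  const int m = Y.ncol();
  const int total = burnin + samples;
  const int nstore = samples / thin;

  // state
  NumericVector theta(n), g(n), delta(m);
  IntegerVector z(m);
  for (int i = 0; i < n; ++i) {
    theta[i] = R::runif(0.2, 0.8);
    g[i] = R::runif(0.2, 0.8);
  }
  for (int k = 0; k < m; ++k) {
    delta[k] = R::runif(0.2, 0.8);
    z[k] = (R::unif_rand() < 0.5) ? 1 : 0;
  }
  double mu_t = 0.5, kap_t = 10.0, mu_g = 0.5, kap_g = 10.0;

  // adaptive proposal log-sds and acceptance bookkeeping
  NumericVector ls_theta(n, std::log(0.5)), ls_g(n, std::log(0.5)),
      ls_delta(m, std::log(0.5));
  double ls_mu_t = std::log(0.3), ls_kap_t = std::log(0.3),
         ls_mu_g = std::log(0.3), ls_kap_g = std::log(0.3);
  double ls_grp_t = std::log(0.1), ls_grp_g = std::log(0.1);
  IntegerVector acc_theta(n), acc_g(n), acc_delta(m);
  int acc_mu_t = 0, acc_kap_t = 0, acc_mu_g = 0, acc_kap_g = 0;
  int acc_grp_t = 0, acc_grp_g = 0;
  IntegerVector tot_theta(n), tot_g(n), tot_delta(m);
  const int batch = 50;

  // posterior-mean accumulators (every post-burn-in iteration)
  NumericVector sum_theta(n), sum_g(n), sum_delta(m), sum_z(m);

  // thinned draws
  NumericMatrix st_theta(nstore, n), st_g(nstore, n), st_delta(nstore, m);
  IntegerMatrix st_z(nstore, m);
  NumericMatrix st_hyper(nstore, 4);
  int stored = 0;

  long acc_theta_post = 0, prop_theta_post = 0;

  for (int it = 0; it < total; ++it) {
    bool adapting = it < burnin;

    // --- theta_i ---
    for (int i = 0; i < n; ++i) {
      double cur = theta[i];
      double prop = inv_logit(logit(cur) + R::norm_rand() * std::exp(ls_theta[i]));
      double ll_cur = 0.0, ll_prop = 0.0;
      for (int k = 0; k < m; ++k) {
        int y = Y(i, k);
        ll_cur += cell_loglik(y, cur, g[i], delta[k], z[k]);
        ll_prop += cell_loglik(y, prop, g[i], delta[k], z[k]);
      }
      double lp_cur = std::log(cur * (1.0 - cur));
      double lp_prop = std::log(prop * (1.0 - prop));
      if (hierarchical) {
        lp_cur += log_dbeta_mu_kappa(cur, mu_t, kap_t);
        lp_prop += log_dbeta_mu_kappa(prop, mu_t, kap_t);
      }
      if (std::log(R::unif_rand()) < (ll_prop + lp_prop) - (ll_cur + lp_cur)) {
        theta[i] = prop;
        acc_theta[i]++;
        if (!adapting) acc_theta_post++;
      }
      tot_theta[i]++;
      if (!adapting) prop_theta_post++;
    }

    // --- g_i ---
    for (int i = 0; i < n; ++i) {
      double cur = g[i];
      double prop = inv_logit(logit(cur) + R::norm_rand() * std::exp(ls_g[i]));
      double ll_cur = 0.0, ll_prop = 0.0;
      for (int k = 0; k < m; ++k) {
        int y = Y(i, k);
        ll_cur += cell_loglik(y, theta[i], cur, delta[k], z[k]);
        ll_prop += cell_loglik(y, theta[i], prop, delta[k], z[k]);
      }
      double lp_cur = std::log(cur * (1.0 - cur));
      double lp_prop = std::log(prop * (1.0 - prop));
      if (hierarchical) {
        lp_cur += log_dbeta_mu_kappa(cur, mu_g, kap_g);
        lp_prop += log_dbeta_mu_kappa(prop, mu_g, kap_g);
      }
      if (std::log(R::unif_rand()) < (ll_prop + lp_prop) - (ll_cur + lp_cur)) {
        g[i] = prop;
        acc_g[i]++;
      }
      tot_g[i]++;
    }

    // --- delta_k (uniform prior) ---
    for (int k = 0; k < m; ++k) {
      double cur = delta[k];
      double prop = inv_logit(logit(cur) + R::norm_rand() * std::exp(ls_delta[k]));
      double ll_cur = 0.0, ll_prop = 0.0;
      for (int i = 0; i < n; ++i) {
        int y = Y(i, k);
        ll_cur += cell_loglik(y, theta[i], g[i], cur, z[k]);
        ll_prop += cell_loglik(y, theta[i], g[i], prop, z[k]);
      }
      double lp_cur = std::log(cur * (1.0 - cur));
      double lp_prop = std::log(prop * (1.0 - prop));
      if (std::log(R::unif_rand()) < (ll_prop + lp_prop) - (ll_cur + lp_cur)) {
        delta[k] = prop;
        acc_delta[k]++;
      }
      tot_delta[k]++;
    }

    // --- z_k, exact Gibbs with Bernoulli(0.5) prior ---
    for (int k = 0; k < m; ++k) {
      double l1 = 0.0, l0 = 0.0;
      for (int i = 0; i < n; ++i) {
        int y = Y(i, k);
        l1 += cell_loglik(y, theta[i], g[i], delta[k], 1);
        l0 += cell_loglik(y, theta[i], g[i], delta[k], 0);
      }
      double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
      z[k] = (R::unif_rand() < p1) ? 1 : 0;
    }

    // --- joint (z_k, delta_k) mode jump ---
    // The conditional Gibbs update of z_k can lock onto one truth
    // configuration because delta_k adapts to it. An independence-style
    // Metropolis move proposing the flipped truth together with a fresh
    // difficulty from its (uniform) prior lets chains hop between modes;
    // prior and proposal densities cancel in the acceptance ratio.
    for (int k = 0; k < m; ++k) {
      int z_prop = 1 - z[k];
      double d_prop = R::runif(0.001, 0.999);
      double ll_cur = 0.0, ll_prop = 0.0;
      for (int i = 0; i < n; ++i) {
        int y = Y(i, k);
        ll_cur += cell_loglik(y, theta[i], g[i], delta[k], z[k]);
        ll_prop += cell_loglik(y, theta[i], g[i], d_prop, z_prop);
      }
      if (std::log(R::unif_rand()) < ll_prop - ll_cur) {
        z[k] = z_prop;
        delta[k] = d_prop;
      }
    }

    // --- hyperparameters ---
    if (hierarchical) {
      // mu_t
      {
        double cur = mu_t;
        double prop = inv_logit(logit(cur) + R::norm_rand() * std::exp(ls_mu_t));
        double lt_cur = std::log(cur * (1.0 - cur));
        double lt_prop = std::log(prop * (1.0 - prop));
        for (int i = 0; i < n; ++i) {
          lt_cur += log_dbeta_mu_kappa(theta[i], cur, kap_t);
          lt_prop += log_dbeta_mu_kappa(theta[i], prop, kap_t);
        }
        if (std::log(R::unif_rand()) < lt_prop - lt_cur) { mu_t = prop; acc_mu_t++; }
      }
      // kappa_t, uniform prior on (2, kappa_max), log-scale walk
      {
        double cur = kap_t;
        double prop = cur * std::exp(R::norm_rand() * std::exp(ls_kap_t));
        if (prop > 2.0 && prop < kappa_max) {
          double lt_cur = std::log(cur), lt_prop = std::log(prop);
          for (int i = 0; i < n; ++i) {
            lt_cur += log_dbeta_mu_kappa(theta[i], mu_t, cur);
            lt_prop += log_dbeta_mu_kappa(theta[i], mu_t, prop);
          }
          if (std::log(R::unif_rand()) < lt_prop - lt_cur) { kap_t = prop; acc_kap_t++; }
        }
      }
      // mu_g
      {
        double cur = mu_g;
        double prop = inv_logit(logit(cur) + R::norm_rand() * std::exp(ls_mu_g));
        double lt_cur = std::log(cur * (1.0 - cur));
        double lt_prop = std::log(prop * (1.0 - prop));
        for (int i = 0; i < n; ++i) {
          lt_cur += log_dbeta_mu_kappa(g[i], cur, kap_g);
          lt_prop += log_dbeta_mu_kappa(g[i], prop, kap_g);
        }
        if (std::log(R::unif_rand()) < lt_prop - lt_cur) { mu_g = prop; acc_mu_g++; }
      }
      // kappa_g
      {
        double cur = kap_g;
        double prop = cur * std::exp(R::norm_rand() * std::exp(ls_kap_g));
        if (prop > 2.0 && prop < kappa_max) {
          double lt_cur = std::log(cur), lt_prop = std::log(prop);
          for (int i = 0; i < n; ++i) {
            lt_cur += log_dbeta_mu_kappa(g[i], mu_g, cur);
            lt_prop += log_dbeta_mu_kappa(g[i], mu_g, prop);
          }
          if (std::log(R::unif_rand()) < lt_prop - lt_cur) { kap_g = prop; acc_kap_g++; }
        }
      }
    }

    // --- group translation moves ---
    // The posterior has a ridge coupling the overall competency level, the
    // overall guessing-bias level and the truth configuration. Shifting a
    // whole respondent-parameter vector (plus its hierarchical mean) by a
    // common logit offset moves along that ridge in one step; per-parameter
    // walks alone mix across it very slowly.
    {
      double eps = R::norm_rand() * std::exp(ls_grp_t);
      double lacc = 0.0;
      std::vector<double> th_new(n);
      for (int i = 0; i < n; ++i) {
        th_new[i] = inv_logit(logit(theta[i]) + eps);
        for (int k = 0; k < m; ++k) {
          int y = Y(i, k);
          lacc += cell_loglik(y, th_new[i], g[i], delta[k], z[k]) -
                  cell_loglik(y, theta[i], g[i], delta[k], z[k]);
        }
        lacc += std::log(th_new[i] * (1.0 - th_new[i])) -
                std::log(theta[i] * (1.0 - theta[i]));
      }
      double mu_new = mu_t;
      if (hierarchical) {
        mu_new = inv_logit(logit(mu_t) + eps);
        for (int i = 0; i < n; ++i) {
          lacc += log_dbeta_mu_kappa(th_new[i], mu_new, kap_t) -
                  log_dbeta_mu_kappa(theta[i], mu_t, kap_t);
        }
        lacc += std::log(mu_new * (1.0 - mu_new)) -
                std::log(mu_t * (1.0 - mu_t));
      }
      if (std::log(R::unif_rand()) < lacc) {
        for (int i = 0; i < n; ++i) theta[i] = th_new[i];
        mu_t = mu_new;
        acc_grp_t++;
      }
    }
    {
      double eps = R::norm_rand() * std::exp(ls_grp_g);
      double lacc = 0.0;
      std::vector<double> g_new(n);
      for (int i = 0; i < n; ++i) {
        g_new[i] = inv_logit(logit(g[i]) + eps);
        for (int k = 0; k < m; ++k) {
          int y = Y(i, k);
          lacc += cell_loglik(y, theta[i], g_new[i], delta[k], z[k]) -
                  cell_loglik(y, theta[i], g[i], delta[k], z[k]);
        }
        lacc += std::log(g_new[i] * (1.0 - g_new[i])) -
                std::log(g[i] * (1.0 - g[i]));
      }
      double mu_new = mu_g;
      if (hierarchical) {
        mu_new = inv_logit(logit(mu_g) + eps);
        for (int i = 0; i < n; ++i) {
          lacc += log_dbeta_mu_kappa(g_new[i], mu_new, kap_g) -
                  log_dbeta_mu_kappa(g[i], mu_g, kap_g);
        }
        lacc += std::log(mu_new * (1.0 - mu_new)) -
                std::log(mu_g * (1.0 - mu_g));
      }
      if (std::log(R::unif_rand()) < lacc) {
        for (int i = 0; i < n; ++i) g[i] = g_new[i];
        mu_g = mu_new;
        acc_grp_g++;
      }
    }

    // --- adapt proposals during burn-in, batches of `batch` iterations ---
    if (adapting && ((it + 1) % batch == 0)) {
      double step = std::min(0.05, 1.0 / std::sqrt((double)(it + 1) / batch));
      for (int i = 0; i < n; ++i) {
        ls_theta[i] += ((double)acc_theta[i] / tot_theta[i] > 0.44) ? step : -step;
        ls_g[i] += ((double)acc_g[i] / tot_g[i] > 0.44) ? step : -step;
        acc_theta[i] = 0; tot_theta[i] = 0;
        acc_g[i] = 0; tot_g[i] = 0;
      }
      for (int k = 0; k < m; ++k) {
        ls_delta[k] += ((double)acc_delta[k] / tot_delta[k] > 0.44) ? step : -step;
        acc_delta[k] = 0; tot_delta[k] = 0;
      }
      if (hierarchical) {
        ls_mu_t += ((double)acc_mu_t / batch > 0.44) ? step : -step;
        ls_kap_t += ((double)acc_kap_t / batch > 0.44) ? step : -step;
        ls_mu_g += ((double)acc_mu_g / batch > 0.44) ? step : -step;
        ls_kap_g += ((double)acc_kap_g / batch > 0.44) ? step : -step;
        acc_mu_t = acc_kap_t = acc_mu_g = acc_kap_g = 0;
      }
      // group moves target a lower acceptance (they are near-global)
      ls_grp_t += ((double)acc_grp_t / batch > 0.25) ? step : -step;
      ls_grp_g += ((double)acc_grp_g / batch > 0.25) ? step : -step;
      acc_grp_t = acc_grp_g = 0;
    }

    // --- accumulate and store ---
    if (!adapting) {
      int post_it = it - burnin;  // 0-based
      for (int i = 0; i < n; ++i) {
        sum_theta[i] += theta[i];
        sum_g[i] += g[i];
      }
      for (int k = 0; k < m; ++k) {
        sum_delta[k] += delta[k];
        sum_z[k] += z[k];
      }
      if ((post_it + 1) % thin == 0 && stored < nstore) {
        for (int i = 0; i < n; ++i) {
          st_theta(stored, i) = theta[i];
          st_g(stored, i) = g[i];
        }
        for (int k = 0; k < m; ++k) {
          st_delta(stored, k) = delta[k];
          st_z(stored, k) = z[k];
        }
        st_hyper(stored, 0) = mu_t;
        st_hyper(stored, 1) = kap_t;
        st_hyper(stored, 2) = mu_g;
        st_hyper(stored, 3) = kap_g;
        stored++;
      }
    }
  }

  double ns = (double)samples;
  return List::create(
      _["theta_mean"] = sum_theta / ns, _["g_mean"] = sum_g / ns,
      _["delta_mean"] = sum_delta / ns, _["z_mean"] = sum_z / ns,
      _["theta_draws"] = st_theta, _["g_draws"] = st_g,
      _["delta_draws"] = st_delta, _["z_draws"] = st_z,
      _["hyper_draws"] = st_hyper,
      _["accept_theta"] = prop_theta_post > 0
                              ? (double)acc_theta_post / prop_theta_post
                              : NA_REAL);
}
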