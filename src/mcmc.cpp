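// Metropolis-within-Gibbs sampler for the state-space growth model.
//
// Target: p(beta, p, n | o) proportional to
//   prod_{t in V} NB(o_t | mu = n_t, size = n_t/(1/p - 1))
//   * prod_{t=2..T} Pois(n_t | lambda_t(n_{t-1}, beta, x_t))
//   * MVN(beta | beta_mean, beta_cov) * Beta(p | s1, s2)
//
// beta: joint Gaussian random-walk Metropolis, proposal covariance adapted
//   to the empirical posterior covariance during burn-in (frozen after).
// n_t: single-site integer random walk in random sweep order; proposals
//   below 1 are auto-rejected (latent support excludes 0).
// p: Metropolis on logit(p) targeting the exact conditional (default), or
//   a pseudo-conjugate Beta draw holding the NB sizes at the current p.
//
// Uses R's RNG so chains are reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double growth_lambda(double n_prev, const arma::vec& beta,
                                   const arma::mat& X, int t,
                                   const arma::uvec& multn) {
  double eta = 0.0;
  for (arma::uword j = 0; j < beta.n_elem; ++j) {
    double x = X(t, j);
    if (multn[j]) x *= n_prev;
    eta += beta[j] * x;
  }
  if (eta > 600.0) return R_PosInf; // overflow guard -> proposal rejected
  return n_prev * std::exp(eta);
}

static inline double proc_ll(double n, double lambda) {
  if (!std::isfinite(lambda) || lambda <= 0.0) return R_NegInf;
  return R::dpois(n, lambda, 1);
}

static inline double obs_ll(double o, double n, double p) {
  double r = n / (1.0 / p - 1.0);
  return R::dnbinom_mu(o, r, n, 1);
}

// Sum of process terms for transitions 2..T (0-based: 1..T-1).
static double process_loglik(const arma::vec& n, const arma::vec& beta,
                             const arma::mat& X, const arma::uvec& multn) {
  double ll = 0.0;
  for (arma::uword t = 1; t < n.n_elem; ++t) {
    ll += proc_ll(n[t], growth_lambda(n[t - 1], beta, X, t, multn));
    if (!std::isfinite(ll)) return R_NegInf;
  }
  return ll;
}

static double observation_loglik(const arma::vec& n, const arma::vec& o,
                                 const arma::ivec& obs, double p) {
  double ll = 0.0;
  for (arma::uword t = 0; t < n.n_elem; ++t) {
    if (obs[t]) ll += obs_ll(o[t], n[t], p);
  }
  return ll;
}

static double mvn_logdens(const arma::vec& beta, const arma::vec& mean,
                          const arma::mat& prec, double logdet_cov) {
  arma::vec d = beta - mean;
  double quad = arma::as_scalar(d.t() * prec * d);
  double k = (double)beta.n_elem;
  return -0.5 * (k * std::log(2.0 * M_PI) + logdet_cov + quad);
}

static double beta_prior_logdens(double p, double s1, double s2) {
  if (p <= 0.0 || p >= 1.0) return R_NegInf;
  return R::dbeta(p, s1, s2, 1);
}

// [[Rcpp::export(name = ".mcmc_chain")]]
List mcmc_chain(NumericVector counts_, IntegerVector observed_,
                arma::mat X, IntegerVector multn_,
                arma::vec beta_mean, arma::mat beta_cov,
                double s1, double s2,
                arma::vec beta_init, double p_init, arma::vec n_init,
                int n_iter, int burn_in, int thin,
                bool do_beta, bool do_p, bool do_latent,
                int p_method, // 0 = metropolis_logit, 1 = pseudo_conjugate
                double target_accept_beta, double target_accept_latent,
                int adapt_window, arma::vec prop_sd_init) {
  const int T = counts_.size();
  const int k = beta_init.n_elem;
  arma::vec o(T), n = n_init;
  arma::ivec obs(T);
  for (int t = 0; t < T; ++t) {
    obs[t] = observed_[t];
    o[t] = obs[t] ? counts_[t] : 0.0;
  }
  arma::uvec multn(k);
  for (int j = 0; j < k; ++j) multn[j] = (multn_[j] != 0);

  arma::mat beta_prec = arma::inv_sympd(beta_cov);
  double logdet_cov, sign;
  arma::log_det(logdet_cov, sign, beta_cov);

  arma::vec beta = beta_init;
  double p = p_init;

  // cached target pieces
  double proc_cur = process_loglik(n, beta, X, multn);
  double obsll_cur = observation_loglik(n, o, obs, p);
  double bprior_cur = mvn_logdens(beta, beta_mean, beta_prec, logdet_cov);
  if (!std::isfinite(proc_cur) || !std::isfinite(obsll_cur)) {
    stop("non-finite log posterior at the initial state");
  }

  // --- adaptation state ---------------------------------------------------
  arma::mat prop_chol = arma::diagmat(prop_sd_init); // pre-adaptation proposal
  double log_s_beta = 0.0;                             // global scale multiplier
  arma::vec run_mean = arma::zeros(k);                 // running moments of beta
  arma::mat run_m2 = arma::zeros(k, k);
  long run_n = 0;
  int acc_beta_win = 0, try_beta_win = 0;
  long acc_beta_tot = 0, try_beta_tot = 0;

  arma::vec lat_scale(T);
  for (int t = 0; t < T; ++t) lat_scale[t] = std::max(2.0, std::sqrt(std::max(n[t], 4.0)) / 2.0);
  arma::ivec acc_lat_win(T, arma::fill::zeros), try_lat_win(T, arma::fill::zeros);
  long acc_lat_tot = 0, try_lat_tot = 0;

  double p_scale = 0.3; // sd of the logit(p) random walk
  int acc_p_win = 0, try_p_win = 0;
  long acc_p_tot = 0, try_p_tot = 0;
  int n_batch = 0;

  // --- storage ------------------------------------------------------------
  const int M = (n_iter - burn_in) / thin;
  arma::mat beta_out(M, k);
  arma::vec p_out(M);
  arma::mat n_out(M, T);
  arma::vec lp_out(M);
  int m = 0;

  std::vector<int> order(T);
  for (int t = 0; t < T; ++t) order[t] = t;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= burn_in;

    // ---- beta block ------------------------------------------------------
    if (do_beta) {
      arma::vec z(k);
      for (int j = 0; j < k; ++j) z[j] = R::norm_rand();
      arma::vec prop = beta + std::exp(log_s_beta) * (prop_chol * z);
      double proc_prop = process_loglik(n, prop, X, multn);
      double bprior_prop = mvn_logdens(prop, beta_mean, beta_prec, logdet_cov);
      double lr = (proc_prop + bprior_prop) - (proc_cur + bprior_cur);
      ++try_beta_win; ++try_beta_tot;
      if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
        beta = prop; proc_cur = proc_prop; bprior_cur = bprior_prop;
        ++acc_beta_win; ++acc_beta_tot;
      }
      if (adapting) { // running moments feed the adapted proposal covariance
        ++run_n;
        arma::vec d = beta - run_mean;
        run_mean += d / (double)run_n;
        run_m2 += d * (beta - run_mean).t();
      }
    }

    // ---- latent block ----------------------------------------------------
    if (do_latent) {
      // Fisher-Yates with R's RNG for a reproducible random sweep order
      for (int t = T - 1; t > 0; --t) {
        int j = (int)std::floor(R::unif_rand() * (t + 1));
        std::swap(order[t], order[j]);
      }
      for (int s = 0; s < T; ++s) {
        int t = order[s];
        double d = std::round(R::norm_rand() * lat_scale[t]);
        if (d == 0.0) continue;
        double n_new = n[t] + d;
        ++try_lat_win[t]; ++try_lat_tot;
        if (n_new < 1.0) continue; // support excludes 0: auto-reject
        double delta = 0.0;
        if (obs[t]) delta += obs_ll(o[t], n_new, p) - obs_ll(o[t], n[t], p);
        if (t > 0) {
          double lam = growth_lambda(n[t - 1], beta, X, t, multn);
          delta += proc_ll(n_new, lam) - proc_ll(n[t], lam);
        }
        if (t < T - 1) {
          delta += proc_ll(n[t + 1], growth_lambda(n_new, beta, X, t + 1, multn)) -
                   proc_ll(n[t + 1], growth_lambda(n[t], beta, X, t + 1, multn));
        }
        if (std::isfinite(delta) && std::log(R::unif_rand()) < delta) {
          n[t] = n_new;
          ++acc_lat_win[t]; ++acc_lat_tot;
        }
      }
      proc_cur = process_loglik(n, beta, X, multn);
      obsll_cur = observation_loglik(n, o, obs, p);
    }

    // ---- p block ---------------------------------------------------------
    if (do_p) {
      if (p_method == 0) { // Metropolis on logit(p), exact conditional
        double l = std::log(p / (1.0 - p));
        double l_new = l + R::norm_rand() * p_scale;
        double p_new = 1.0 / (1.0 + std::exp(-l_new));
        ++try_p_win; ++try_p_tot;
        if (p_new > 0.0 && p_new < 1.0) {
          double obs_new = observation_loglik(n, o, obs, p_new);
          // prior + log-Jacobian of the logit transform: + log p(1-p)
          double lr = (obs_new + beta_prior_logdens(p_new, s1, s2) +
                       std::log(p_new) + std::log1p(-p_new)) -
                      (obsll_cur + beta_prior_logdens(p, s1, s2) +
                       std::log(p) + std::log1p(-p));
          if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
            p = p_new; obsll_cur = obs_new;
            ++acc_p_win; ++acc_p_tot;
          }
        }
      } else { // pseudo-conjugate Beta draw, sizes r_t held at current p
        double r_sum = 0.0, o_sum = 0.0;
        for (int t = 0; t < T; ++t) {
          if (obs[t]) { r_sum += n[t] / (1.0 / p - 1.0); o_sum += o[t]; }
        }
        p = R::rbeta(s1 + r_sum, s2 + o_sum);
        p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
        obsll_cur = observation_loglik(n, o, obs, p);
        ++try_p_win; ++try_p_tot; ++acc_p_win; ++acc_p_tot;
      }
    }

    // ---- adaptation (burn-in only; frozen afterwards) ---------------------
    if (adapting && iter % adapt_window == 0) {
      ++n_batch;
      double step = 1.0 / std::sqrt((double)n_batch);
      if (do_beta && try_beta_win > 0) {
        double acc = (double)acc_beta_win / (double)try_beta_win;
        log_s_beta += step * (acc - target_accept_beta);
        if (run_n > std::max(200L, 10L * (long)k)) {
          arma::mat emp = run_m2 / (double)(run_n - 1);
          emp.diag() += 1e-12 + 1e-6 * arma::square(prop_sd_init);
          arma::mat C;
          if (arma::chol(C, (5.6644 / (double)k) * emp, "lower")) prop_chol = C;
        }
        acc_beta_win = try_beta_win = 0;
      }
      if (do_latent) {
        for (int t = 0; t < T; ++t) {
          if (try_lat_win[t] > 0) {
            double acc = (double)acc_lat_win[t] / (double)try_lat_win[t];
            lat_scale[t] *= std::exp(step * (acc - target_accept_latent));
            lat_scale[t] = std::min(std::max(lat_scale[t], 0.6), 1e6);
          }
          acc_lat_win[t] = try_lat_win[t] = 0;
        }
      }
      if (do_p && p_method == 0 && try_p_win > 0) {
        double acc = (double)acc_p_win / (double)try_p_win;
        p_scale *= std::exp(step * (acc - 0.44));
        p_scale = std::min(std::max(p_scale, 1e-4), 10.0);
        acc_p_win = try_p_win = 0;
      }
    }

    // ---- record ----------------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0 && m < M) {
      beta_out.row(m) = beta.t();
      p_out[m] = p;
      n_out.row(m) = n.t();
      lp_out[m] = proc_cur + obsll_cur + bprior_cur +
                  beta_prior_logdens(p, s1, s2);
      ++m;
    }
  }

  return List::create(
    _["beta"] = beta_out, _["p"] = p_out, _["latent"] = n_out,
    _["log_post"] = lp_out,
    _["accept"] = List::create(
      _["beta"] = try_beta_tot ? (double)acc_beta_tot / try_beta_tot : NA_REAL,
      _["latent"] = try_lat_tot ? (double)acc_lat_tot / try_lat_tot : NA_REAL,
      _["p"] = try_p_tot ? (double)acc_p_tot / try_p_tot : NA_REAL),
    _["scales"] = List::create(
      _["beta_log_s"] = log_s_beta, _["latent"] = NumericVector(lat_scale.begin(), lat_scale.end()),
      _["p_logit_sd"] = p_scale)
  );
}
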