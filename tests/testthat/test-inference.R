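test_that("draw bookkeeping follows the burn-in/thinning rule", {
  cfg <- mcmc_config(n_chains = 2, n_iter = 210000L, burn_in = 10001L, thin = 200L)
  expect_identical(n_retained(cfg), 999L)
  expect_identical(n_retained(mcmc_config(n_iter = 1000, burn_in = 200, thin = 10)), 80L)
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in < n_iter")

  # an actual run retains exactly that many draws per chain
  d <- tiny_data(T = 6)
  fit <- quick_fit(d, model_spec(), n_iter = 730, burn_in = 101, thin = 7)
  expect_identical(dim(fit$beta)[1], (730L - 101L) %/% 7L)
})

test_that("the sampler is deterministic given seed and config", {
  d <- tiny_data(T = 8)
  sp <- model_spec(dd = TRUE)
  f1 <- quick_fit(d, sp, n_iter = 2000, burn_in = 500, thin = 5, seed = 123)
  f2 <- quick_fit(d, sp, n_iter = 2000, burn_in = 500, thin = 5, seed = 123)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$latent, f2$latent)
  expect_identical(f1$p, f2$p)
  f3 <- quick_fit(d, sp, n_iter = 2000, burn_in = 500, thin = 5, seed = 124)
  expect_false(identical(f1$beta, f3$beta))
})

test_that("cached chain log-posterior equals a fresh R recomputation", {
  d <- tiny_data(T = 7, missing = 3L)
  sp <- model_spec(dd = TRUE, covariates = "Temp")
  fit <- quick_fit(d, sp, n_iter = 3000, burn_in = 1000, thin = 20)
  pool <- guanacoSSM:::pool_draws(fit)
  for (m in c(1L, 57L, length(pool$p))) {
    expect_equal(
      pool$log_post[m],
      log_posterior(d$counts, pool$latent[m, ], pool$beta[m, ], pool$p[m],
                    fit$X, sp, fit$priors),
      tolerance = 1e-10
    )
  }
})

test_that("beta conditional matches a 1-D quadrature oracle on a fixed-latent toy", {
  # Latents and p held fixed: the intercept-only conditional posterior
  # p(b0 | n) ~ prod_t Pois(n_t | n_{t-1} e^{b0}) N(b0; 0, 1) is a smooth
  # 1-D density we can integrate on a grid.
  sp <- model_spec()
  X <- build_design(sp, list(), 6)
  latent <- c(40, 46, 50, 58, 66, 70)
  counts <- rep(NA_integer_, 6) # no observation terms: isolate the beta move
  pr <- ssm_priors(sp)

  grid <- seq(-0.5, 0.8, length.out = 4001)
  lp <- sapply(grid, function(b) {
    sum(dpois(latent[-1], latent[-6] * exp(b), log = TRUE)) + dnorm(b, 0, 1, log = TRUE)
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  oracle_mean <- sum(grid * w)
  oracle_sd <- sqrt(sum((grid - oracle_mean)^2 * w))

  fit <- run_mcmc(counts, X, sp, priors = pr,
                  config = mcmc_config(n_chains = 2, n_iter = 30000,
                                       burn_in = 5000, thin = 5, seed = 2),
                  update_p = FALSE, update_latent = FALSE,
                  init = list(latent = latent, p = 0.5))
  draws <- as.vector(fit$beta[, 1, ])
  mc_se <- sd(draws) / sqrt(200) # conservative ESS guess for an RW chain
  expect_lt(abs(mean(draws) - oracle_mean), 3 * mc_se + 1e-3)
  expect_equal(sd(draws), oracle_sd, tolerance = 0.1)
})

test_that("disabled update blocks leave their components frozen", {
  d <- tiny_data(T = 5)
  sp <- model_spec()
  covs <- prepare_covariates(d)
  X <- build_design(sp, covs, 5)
  fit <- run_mcmc(d$counts, X, sp,
                  config = mcmc_config(n_chains = 1, n_iter = 500, burn_in = 100,
                                       thin = 2, seed = 1),
                  update_beta = FALSE, update_p = FALSE,
                  init = list(beta = 0.02, p = 0.6))
  expect_equal(var(fit$beta[, 1, 1]), 0) # chain never moves
  expect_true(all(fit$beta[, 1, 1] == 0.02))
  expect_true(all(fit$p == 0.6))
  expect_gt(var(as.vector(fit$latent[, 3, ])), 0) # active block still mixes
})

test_that("p conditional matches quadrature, and both p samplers agree", {
  # fixed latents: p(p | n, o) ~ prod_{t in V} NB(o_t | n_t, p) Beta(p; 1, 1)
  sp <- model_spec()
  X <- build_design(sp, list(), 5)
  latent <- c(500, 520, 540, 560, 580)
  counts <- c(480L, 560L, 520L, 610L, 540L)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 8001)
  lp <- sapply(grid, function(p) sum(obs_loglik(counts, latent, p)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  oracle_mean <- sum(grid * w)

  fits <- lapply(c("metropolis_logit", "pseudo_conjugate"), function(meth) {
    run_mcmc(counts, X, sp,
             config = mcmc_config(n_chains = 2, n_iter = 20000, burn_in = 4000,
                                  thin = 4, seed = 31),
             p_method = meth, update_beta = FALSE, update_latent = FALSE,
             init = list(latent = latent, beta = 0.01))
  })
  p_means <- sapply(fits, function(f) mean(f$p))
  mc_se <- sd(fits[[1]]$p) / sqrt(200)
  expect_lt(abs(p_means[1] - oracle_mean), 3 * mc_se + 5e-3)

  # The pseudo-conjugate chain (sizes r_t frozen at the current p) is not
  # exact: its expectation map p -> (s1 + sum r_t)/(s1 + s2 + sum r_t +
  # sum o_t) contracts, for s1 = s2 = 1, onto the fixed point
  # p* = 1/(2 + sum o_t - sum n_t). Check the implementation lands there.
  p_star <- 1 / (2 + sum(counts) - sum(latent))
  expect_lt(abs(p_means[2] - p_star), 0.02)
})

test_that("with no observed years p relaxes to its Beta prior", {
  sp <- model_spec()
  X <- build_design(sp, list(), 4)
  counts <- rep(NA_integer_, 4)
  pr <- ssm_priors(sp, s1 = 3, s2 = 2)
  fit <- run_mcmc(counts, X, sp, priors = pr,
                  config = mcmc_config(n_chains = 2, n_iter = 20000,
                                       burn_in = 2000, thin = 4, seed = 6),
                  update_beta = FALSE, update_latent = FALSE,
                  init = list(latent = c(50, 50, 50, 50), beta = 0))
  draws <- as.vector(fit$p)
  expect_equal(mean(draws), 3 / 5, tolerance = 0.02) # Beta(3,2) mean
  expect_equal(var(draws), 3 * 2 / (25 * 6), tolerance = 0.15)
})

test_that("latent updates under near-perfect detection concentrate on the count", {
  sp <- model_spec()
  X <- build_design(sp, list(), 3)
  counts <- c(200L, 205L, 210L)
  fit <- run_mcmc(counts, X, sp,
                  config = mcmc_config(n_chains = 2, n_iter = 10000,
                                       burn_in = 2000, thin = 4, seed = 9),
                  update_beta = FALSE, update_p = FALSE,
                  init = list(beta = 0.01, p = 0.995))
  mode2 <- as.numeric(names(which.max(table(fit$latent[, 2, ]))))
  expect_lt(abs(mode2 - counts[2]), 2.5)
})

test_that("MCMC latent marginals match exhaustive enumeration on a 2-year toy", {
  # fixed beta and p; support effectively bounded by 60. The stationary
  # distribution of the latent sweep must match the brute-force posterior.
  sp <- model_spec()
  X <- build_design(sp, list(), 2)
  counts <- c(10L, 12L)
  beta <- 0; p <- 0.7
  enum <- enumerate_latent_posterior(counts, beta, p, X, sp, n_max = 60)

  fit <- run_mcmc(counts, X, sp,
                  config = mcmc_config(n_chains = 2, n_iter = 60000,
                                       burn_in = 5000, thin = 2, seed = 13),
                  update_beta = FALSE, update_p = FALSE,
                  init = list(beta = beta, p = p))
  for (t in 1:2) {
    draws <- factor(as.vector(fit$latent[, t, ]), levels = 1:60)
    emp <- as.numeric(table(draws)) / length(draws)
    tv <- 0.5 * sum(abs(emp - as.numeric(enum$marginals[[t]])))
    expect_lt(tv, 0.05)
  }
})

test_that("potential scale reduction behaves across regimes", {
  m <- 400
  set.seed(5)
  base <- rnorm(m)
  # identical chains: B = 0 gives sqrt((m-1)/m) < 1
  expect_equal(psrf(cbind(base, base)), sqrt((m - 1) / m))
  # same-distribution chains approach 1
  expect_lt(abs(psrf(matrix(rnorm(m * 4), m, 4)) - 1), 0.05)
  # separated chains blow up
  expect_gt(psrf(cbind(base - 10, base + 10)), 5)

  d <- tiny_data(T = 6)
  fit <- quick_fit(d, model_spec(), n_iter = 4000, burn_in = 1000, thin = 5)
  r <- psrf(fit)
  expect_named(r, c("(Intercept)", "p"))
  expect_true(all(is.finite(r)))
  rl <- psrf(fit, include_latent = TRUE)
  expect_identical(length(rl), 2L + 6L)

  f1 <- quick_fit(d, model_spec(), n_chains = 1)
  expect_error(psrf(f1), "at least 2 chains")
})

test_that("initialization failures name the offending year", {
  sp <- model_spec()
  X <- build_design(sp, list(), 4)
  counts <- c(100L, 110L, 120L, 130L)
  # an absurd starting growth rate overflows the exponent at the first
  # transition: the error must point at year 2 rather than crash later
  expect_error(
    run_mcmc(counts, X, sp,
             config = mcmc_config(n_chains = 1, n_iter = 200, burn_in = 50, thin = 1),
             init = list(beta = 800)),
    "offending year index: 2"
  )
})
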