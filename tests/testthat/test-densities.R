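test_that("growth expectation evaluates the Ricker/covariate exponent", {
  sp0 <- model_spec()
  expect_equal(growth_expectation(500, 0, 1, sp0), 500) # exp(0) = 1

  spd <- model_spec(dd = TRUE)
  beta <- c(0.1, -1e-5)
  expect_equal(growth_expectation(1000, beta, c(1, 1), spd), 1000 * exp(0.09))
  # equilibrium identity: lambda(K) = K at K = -b0/b1
  K <- -beta[1] / beta[2]
  expect_equal(growth_expectation(K, beta, c(1, 1), spd), K)

  # interaction term multiplies covariate by previous abundance
  spi <- model_spec(dd = TRUE, covariates = "Temp", interactions = "Temp")
  b <- c(0.2, -2e-6, 0.05, -1e-6)
  x <- c(1, 1, 0.7, 0.7)
  n <- 1500
  expect_equal(growth_expectation(n, b, x, spi),
               n * exp(0.2 - 2e-6 * n + 0.05 * 0.7 - 1e-6 * 0.7 * n))

  expect_error(growth_expectation(0.5, 0, 1, sp0), ">= 1")
  expect_error(growth_expectation(1e4, c(1, 0.1), c(1, 1), spd), "overflow")
})

test_that("observation model is a proper NB with mean n and variance n/p", {
  # normalization at moderate n
  o <- 0:2000
  expect_equal(sum(exp(obs_loglik(o, 20, 0.6))), 1, tolerance = 1e-8)

  # moment oracle by direct summation: mean n, variance n/p
  for (n in c(10, 50)) {
    for (p in c(0.3, 0.5, 0.9)) {
      o <- 0:5000
      pm <- exp(obs_loglik(o, n, p))
      m1 <- sum(o * pm)
      v <- sum((o - m1)^2 * pm)
      expect_equal(m1, n, tolerance = 1e-6)
      expect_equal(v, n / p, tolerance = 1e-6)
    }
  }

  # detection-probability convention: mass equals C(o+r-1, o) p^r (1-p)^o
  n <- 12; p <- 0.35; r <- n / (1 / p - 1)
  expect_equal(obs_loglik(7, n, p),
               lchoose(7 + r - 1, 7) + r * log(p) + 7 * log(1 - p),
               tolerance = 1e-10)

  expect_error(obs_loglik(3, 10, 1), "strictly in")
  expect_error(obs_loglik(-1, 10, 0.5), "nonnegative")
})

test_that("NB converges to the Poisson as detection approaches 1", {
  n <- 30
  # log-density agreement at the mean
  expect_lt(abs(obs_loglik(n, n, 0.999) - dpois(n, n, log = TRUE)), 1e-3)
  # pmf-scale sup norm over o <= 5n at p = 0.9999
  o <- 0:(5 * n)
  expect_lt(max(abs(exp(obs_loglik(o, n, 0.9999)) - dpois(o, n))), 1e-3)
})

test_that("process model is the Poisson mass", {
  expect_equal(proc_loglik(1, 1), -1) # e^{-1} * 1 / 1!
  expect_equal(sum(exp(proc_loglik(0:200, 5))), 1, tolerance = 1e-10)
  # mode at floor(lambda) for non-integer lambda
  expect_equal(which.max(proc_loglik(0:30, 7.5)) - 1L, 7L)
  expect_error(proc_loglik(3, -1), "positive")
  expect_error(proc_loglik(2.5, 3), "integer")
})

test_that("joint likelihood decomposes and matches the independent oracle", {
  sp <- model_spec(dd = TRUE, covariates = "Temp")
  T <- 3
  X <- build_design(sp, list(Temp = c(-0.5, 0.2, 0.9)), T, lag = 0)
  beta <- c(0.15, -5e-4, 0.08)
  p <- 0.7
  latent <- c(120, 140, 150)
  counts <- c(118, NA, 160)

  # matches a separately coded term-by-term summation
  expect_equal(
    joint_loglik(counts, latent, beta, p, X, sp),
    oracle_joint_loglik(counts, latent, beta, p, X, attr(X, "mult_by_n")),
    tolerance = 1e-12
  )

  # no observed years: pure process likelihood
  none <- rep(NA_integer_, T)
  lam <- sapply(2:T, function(t) growth_expectation(latent[t - 1], beta, X[t, ], sp))
  expect_equal(joint_loglik(none, latent, beta, p, X, sp),
               sum(proc_loglik(latent[2:T], lam)))

  # T=2 with one observed year: process + observation computed separately
  sp0 <- model_spec()
  X2 <- build_design(sp0, list(), 2)
  expect_equal(joint_loglik(c(NA, 45), c(50, 48), 0.1, p, X2, sp0),
               proc_loglik(48, 50 * exp(0.1)) + obs_loglik(45, 48, p))

  # invariant to the values stored at masked years
  cnt2 <- counts
  cnt2[2] <- NA # already NA; also check mask drives the sum, not the value
  expect_equal(joint_loglik(counts, latent, beta, p, X, sp),
               joint_loglik(cnt2, latent, beta, p, X, sp))

  expect_error(joint_loglik(counts, latent[1:2], beta, p, X, sp), "differ")
})

test_that("priors and posterior compose additively", {
  sp <- model_spec()
  pr <- ssm_priors(sp)
  # standard normal peak for k = 1 at the prior mean, uniform p prior at 0.5
  expect_equal(log_prior(0, 0.5, pr), -0.5 * log(2 * pi))
  expect_equal(dbeta(0.5, pr$s1, pr$s2, log = TRUE), 0)
  expect_identical(log_prior(0, 1, pr), -Inf)
  expect_identical(log_prior(0, 0, pr), -Inf)

  # k = 2 general case against an explicit quadratic form
  sp2 <- model_spec(dd = TRUE)
  pr2 <- ssm_priors(sp2)
  pr2$beta_cov <- matrix(c(2, 0.3, 0.3, 0.5), 2)
  beta <- c(0.4, -0.1)
  mu <- pr2$beta_mean
  S <- pr2$beta_cov
  direct <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * t(beta - mu) %*% solve(S) %*% (beta - mu)
  expect_equal(log_prior(beta, 0.5, pr2) - dbeta(0.5, 1, 1, log = TRUE),
               as.numeric(direct), tolerance = 1e-12)

  # posterior = likelihood + prior on a toy instance
  T <- 3
  X <- build_design(sp2, list(), T)
  latent <- c(30, 33, 31)
  counts <- c(28, NA, 35)
  b <- c(0.05, -1e-4)
  expect_equal(
    log_posterior(counts, latent, b, 0.6, X, sp2, pr2),
    joint_loglik(counts, latent, b, 0.6, X, sp2) + log_prior(b, 0.6, pr2)
  )
})

test_that("carrying capacity is the fixed point of the growth expectation", {
  spd <- model_spec(dd = TRUE)
  expect_equal(carrying_capacity(c(0.2, -4e-6), spd), 50000)

  # fixed-point property with covariates and interactions
  sp <- model_spec(dd = TRUE, covariates = c("Temp", "Sheep"), interactions = "Temp")
  beta <- c(0.18, -3e-6, 0.05, -0.12, -4e-7)
  xbar <- c(Temp = 0.4, Sheep = 0.8)
  K <- carrying_capacity(beta, sp, xbar)
  xrow <- c(1, 1, xbar[["Temp"]], xbar[["Sheep"]], xbar[["Temp"]])
  expect_equal(growth_expectation(K, beta, xrow, sp), K, tolerance = 1e-9)

  # reduces to -(b0 + sum b_j xbar_j)/b1 without interactions
  sp2 <- model_spec(dd = TRUE, covariates = "Sheep")
  expect_equal(carrying_capacity(c(0.2, -4e-6, -0.1), sp2, c(Sheep = 1)),
               -(0.2 - 0.1) / (-4e-6))

  expect_error(carrying_capacity(0.2, model_spec()), "K undefined")
  expect_error(carrying_capacity(c(0.2, 4e-6), spd), "no stable equilibrium")
  expect_error(carrying_capacity(c(0.2, -4e-6, -0.1), sp2), "xbar")
})
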