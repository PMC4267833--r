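# Shared fixtures: tiny datasets built in code, and independent oracle
# implementations kept deliberately naive (straightforward summation,
# no reuse of package internals) so they can vouch for the fast paths.

# A minimal complete dataset: deterministic covariates, hand-set counts.
tiny_data <- function(T = 8, counts = NULL, missing = integer()) {
  if (is.null(counts)) counts <- round(seq(100, 300, length.out = T))
  counts[missing] <- NA
  guanacoSSM:::new_dataset(
    years = 2000L + seq_len(T) - 1L,
    counts = counts,
    winter_temp = 3 + sin(seq_len(T)),
    precip = 350 + 10 * cos(seq_len(T)),
    sheep_year = 2000L + c(0L, T %/% 2L, T - 1L),
    sheep_count = c(30000, 35000, 32000)
  )
}

# Independent joint log-likelihood: direct term-by-term summation using
# stats d* densities and the model definition, nothing shared with
# joint_loglik() beyond the density formulas themselves.
oracle_joint_loglik <- function(counts, latent, beta, p, X, mult_by_n) {
  ll <- 0
  for (t in seq_along(latent)) {
    if (!is.na(counts[t])) {
      r <- latent[t] / (1 / p - 1)
      ll <- ll + dnbinom(counts[t], size = r, mu = latent[t], log = TRUE)
    }
    if (t >= 2) {
      x <- X[t, ]
      x[mult_by_n] <- x[mult_by_n] * latent[t - 1]
      lambda <- latent[t - 1] * exp(sum(beta * x))
      ll <- ll + dpois(latent[t], lambda, log = TRUE)
    }
  }
  ll
}

# Exhaustive enumeration of the latent posterior on a T-year toy with
# bounded support, for fixed beta and p. Returns the joint array and the
# per-year marginals.
enumerate_latent_posterior <- function(counts, beta, p, X, spec, n_max = 60) {
  Tn <- length(counts)
  grids <- rep(list(seq_len(n_max)), Tn)
  joint <- do.call(expand.grid, grids)
  lp <- apply(as.matrix(joint), 1, function(n) {
    joint_loglik(counts, n, beta, p, X, spec)
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  marg <- lapply(seq_len(Tn), function(t) {
    tapply(w, joint[[t]], sum)
  })
  list(weights = w, joint = joint, marginals = marg)
}

# Quick fit wrapper with small chains for structural tests.
quick_fit <- function(data, spec, n_iter = 6000, burn_in = 2000, thin = 10,
                      n_chains = 2, seed = 42, ...) {
  covs <- prepare_covariates(data)
  X <- build_design(spec, covs, length(data$years))
  run_mcmc(data$counts, X, spec,
           config = mcmc_config(n_chains = n_chains, n_iter = n_iter,
                                burn_in = burn_in, thin = thin, seed = seed),
           ...)
}
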