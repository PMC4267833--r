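# Hierarchical model densities. Everything is computed in log space.
#
# Observation model: counts o_t | n_t ~ NegBin with mean n_t and size
#   r_t = n_t / (1/p - 1), so var(o_t | n_t) = n_t / p; p in (0,1) is the
#   per-individual detection probability governing overdispersion.
# Process model: n_t | n_{t-1} ~ Poisson(lambda_t) with
#   lambda_t = n_{t-1} * exp(beta' x_eff), the (covariate-dependent) Ricker
#   growth expectation.

#' Expected population size under the growth model
#'
#' Evaluates `lambda = n_prev * exp(b0 + b1*n_prev + sum_j b_j x_j +
#' sum_j g_j x_j n_prev)`, the one-step growth expectation: exponential
#' growth, optionally damped by density dependence (Ricker) and modulated
#' by covariates and covariate-by-density interactions.
#'
#' @param n_prev previous abundance (scalar, >= 1).
#' @param beta numeric vector of growth parameters, aligned to the design
#'   columns of `spec`.
#' @param x_row one row of the design matrix (length `spec$k`).
#' @param spec an [model_spec()].
#' @return The positive scalar expectation `lambda`.
#' @examples
#' sp <- model_spec(dd = TRUE)
#' growth_expectation(1000, c(0.1, -1e-5), c(1, 1), sp) # 1000*exp(0.09)
#' @export
growth_expectation <- function(n_prev, beta, x_row, spec) {
  stopifnot(inherits(spec, "ssm_spec"))
  if (!is.numeric(n_prev) || length(n_prev) != 1L || n_prev < 1) {
    stop("n_prev must be a scalar abundance >= 1")
  }
  if (length(beta) != spec$k || length(x_row) != spec$k) {
    stop("beta and x_row must have length k = ", spec$k)
  }
  cols <- spec_columns(spec)
  x_eff <- x_row * ifelse(cols$mult_by_n, n_prev, 1)
  terms <- beta * x_eff
  eta <- sum(terms)
  if (!is.finite(eta) || eta + log(n_prev) > log(.Machine$double.xmax)) {
    worst <- which.max(abs(terms))
    stop("growth exponent overflow; dominant term: ", cols$names[worst],
         " = ", format(terms[worst]))
  }
  n_prev * exp(eta)
}

#' Negative-binomial observation log-likelihood
#'
#' Log mass of an observed count given the latent abundance, under the
#' overdispersed counting model with mean `n` and size `r = n/(1/p - 1)`
#' (variance `n/p`). Equivalent success-probability form:
#' `C(o + r - 1, o) p^r (1-p)^o`.
#'
#' @param o observed count(s), nonnegative integer.
#' @param n latent abundance(s), >= 1.
#' @param p detection probability, strictly inside (0, 1).
#' @return Log density (vectorized over `o`/`n`).
#' @export
obs_loglik <- function(o, n, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("detection probability p must lie strictly in (0, 1)")
  }
  if (any(o < 0) || any(o != floor(o))) stop("counts must be nonnegative integers")
  if (any(n < 1)) stop("latent abundance must be >= 1")
  dnbinom(o, size = n / (1 / p - 1), mu = n, log = TRUE)
}

#' Poisson process log-likelihood
#'
#' Log mass of a latent abundance given its growth expectation.
#'
#' @param n abundance, nonnegative integer (support excludes 0 in the
#'   sampler, but the density itself is the full Poisson mass).
#' @param lambda positive expectation from [growth_expectation()].
#' @return Log density (vectorized).
#' @export
proc_loglik <- function(n, lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("lambda must be positive and finite")
  if (any(n < 0) || any(n != floor(n))) stop("abundance must be a nonnegative integer")
  dpois(n, lambda, log = TRUE)
}

# Normalize the counts argument: accept a plain vector (NA = unobserved) or
# a dataset-like list carrying $counts.
.get_counts <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$counts)) return(dataset$counts)
  dataset
}

#' Joint log-likelihood of counts and latent trajectory
#'
#' Sum of observation terms over the observed years V (counts present) and
#' Poisson process terms for each transition `t-1 -> t`, `t = 2..T`. Years
#' with a missing count contribute process terms only.
#'
#' @param dataset a dataset object or a plain count vector with `NA` for
#'   unobserved years.
#' @param latent integer latent abundances, length `T`.
#' @param beta growth parameters.
#' @param p detection probability.
#' @param X design matrix from [build_design()] (row `t` feeds the
#'   transition into year `t`).
#' @param spec the growth [model_spec()].
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(dataset, latent, beta, p, X, spec) {
  o <- .get_counts(dataset)
  Tn <- length(latent)
  if (length(o) != Tn) stop("counts and latent trajectory lengths differ (", length(o), " vs ", Tn, ")")
  if (nrow(X) != Tn) stop("design matrix has ", nrow(X), " rows but T = ", Tn)
  if (any(latent < 1) || any(latent != floor(latent))) stop("latent abundances must be integers >= 1")
  V <- which(!is.na(o))
  ll <- 0
  if (length(V)) ll <- sum(obs_loglik(o[V], latent[V], p))
  if (Tn >= 2) {
    lam <- vapply(2:Tn, function(t) {
      growth_expectation(latent[t - 1], beta, X[t, ], spec)
    }, numeric(1))
    ll <- ll + sum(proc_loglik(latent[2:Tn], lam))
  }
  ll
}

#' Log prior density for growth parameters and detection probability
#'
#' Multivariate normal prior on `beta` plus a Beta(s1, s2) prior on `p`.
#' `p` on the boundary of (0, 1) returns `-Inf`.
#'
#' @param beta growth parameter vector.
#' @param p detection probability.
#' @param priors a [ssm_priors()] list with `beta_mean`, `beta_cov`,
#'   `s1`, `s2`.
#' @return Scalar log density.
#' @export
log_prior <- function(beta, p, priors) {
  k <- length(beta)
  stopifnot(length(priors$beta_mean) == k, all(dim(priors$beta_cov) == k))
  if (p <= 0 || p >= 1) return(-Inf)
  L <- chol(priors$beta_cov)
  z <- backsolve(L, beta - priors$beta_mean, transpose = TRUE)
  lmvn <- -0.5 * k * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
  lmvn + dbeta(p, priors$s1, priors$s2, log = TRUE)
}

#' Log posterior (up to the normalizing constant)
#'
#' @inheritParams joint_loglik
#' @inheritParams log_prior
#' @return `joint_loglik(...) + log_prior(...)`.
#' @export
log_posterior <- function(dataset, latent, beta, p, X, spec, priors) {
  joint_loglik(dataset, latent, beta, p, X, spec) + log_prior(beta, p, priors)
}

#' Default priors for a growth model
#'
#' Standard-normal priors for the intercept and covariate effects. Slopes
#' that multiply abundance (the DD slope and interaction slopes) get a
#' standard-normal prior on abundance scaled by 1e-4, i.e. sd 1e-4 on the
#' natural per-individual scale. Detection probability defaults to the
#' uniform Beta(1, 1).
#'
#' @param spec an [model_spec()].
#' @param sd_intercept,sd_covariate,sd_dd prior standard deviations.
#' @param s1,s2 beta-prior shapes for `p`.
#' @return A list of class `ssm_priors`.
#' @export
ssm_priors <- function(spec, sd_intercept = 1, sd_covariate = 1, sd_dd = 1e-4,
                       s1 = 1, s2 = 1) {
  cols <- spec_columns(spec)
  sds <- ifelse(cols$mult_by_n, sd_dd, sd_covariate)
  sds[1] <- sd_intercept
  structure(
    list(
      beta_mean = setNames(rep(0, spec$k), cols$names),
      beta_cov = diag(sds^2, nrow = spec$k),
      beta_sd = sds,
      s1 = s1, s2 = s2
    ),
    class = "ssm_priors"
  )
}

#' Carrying capacity implied by a Ricker-type model
#'
#' At equilibrium the growth exponent is zero, giving
#' `K = -(b0 + sum_j b_j xbar_j) / (b1 + sum_j g_j xbar_j)` where `xbar_j`
#' are average covariate values over the interval of interest (main-effect
#' covariates enter the numerator, interaction covariates the denominator).
#' `K` is a fixed point of [growth_expectation()] evaluated at the mean
#' covariates.
#'
#' @param beta growth parameter vector.
#' @param spec the growth [model_spec()]; must contain density dependence
#'   (a DD main effect or at least one interaction term).
#' @param xbar named numeric vector of covariate means on the transformed
#'   scale, covering every covariate in the model (may be empty for the
#'   plain Ricker model).
#' @return The scalar carrying capacity.
#' @examples
#' carrying_capacity(c(0.2, -4e-6), model_spec(dd = TRUE)) # 50000
#' @export
carrying_capacity <- function(beta, spec, xbar = numeric()) {
  stopifnot(inherits(spec, "ssm_spec"), length(beta) == spec$k)
  if (!spec$has_dd && !length(spec$interactions)) {
    stop("K undefined for exponential models (no density-dependence term)")
  }
  cols <- spec_columns(spec)
  beta <- setNames(as.numeric(beta), cols$names)
  need <- union(spec$covariates, spec$interactions)
  missing_cov <- setdiff(need, names(xbar))
  if (length(missing_cov)) {
    stop("xbar must supply mean(s) for: ", paste(missing_cov, collapse = ", "))
  }
  num <- beta[["(Intercept)"]] +
    sum(vapply(spec$covariates, function(cv) beta[[cv]] * xbar[[cv]], numeric(1)))
  den <- (if (spec$has_dd) beta[["DD"]] else 0) +
    sum(vapply(spec$interactions, function(cv) beta[[paste0(cv, ":DD")]] * xbar[[cv]], numeric(1)))
  if (den >= 0) stop("no stable equilibrium: density-dependence denominator is nonnegative")
  -num / den
}
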