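# Multi-chain Metropolis-within-Gibbs over (beta, p, n_1..n_T), with
# burn-in adaptation, thinning and Gelman-Rubin diagnostics. The per-chain
# inner loop lives in src/mcmc.cpp; this file owns configuration,
# initialization, bookkeeping and output containers.

#' MCMC configuration
#'
#' @param n_chains number of parallel chains (>= 2 for convergence
#'   diagnostics). The reference configuration of the analysis is 10
#'   chains of 210,000 iterations, burn-in 10,001, thinning 200 (999
#'   retained draws per chain); defaults here are a lighter setting for
#'   desk-scale work.
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded (adaptation happens here and
#'   proposal scales are frozen afterwards).
#' @param thin keep every `thin`-th iteration after burn-in.
#' @param seed base integer seed; chain `c` uses `seed + 7919 * (c - 1)`.
#' @param adapt_window iterations between proposal-scale updates.
#' @param target_accept target acceptance rate for the joint beta block.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 50000L, burn_in = 10000L,
                        thin = 40L, seed = 1L, adapt_window = 50L,
                        target_accept = 0.3) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed), adapt_window = as.integer(adapt_window),
         target_accept = target_accept),
    class = "mcmc_config"
  )
}

#' Retained draws per chain for a configuration
#'
#' Draws are recorded at iterations `i > burn_in` with
#' `(i - burn_in) %% thin == 0`, hence `floor((n_iter - burn_in)/thin)`
#' per chain.
#'
#' @param config an [mcmc_config()].
#' @return Integer draw count.
#' @export
n_retained <- function(config) {
  as.integer((config$n_iter - config$burn_in) %/% config$thin)
}

# Initial latent trajectory: observed counts with gaps filled linearly.
init_latent <- function(counts) {
  Tn <- length(counts)
  V <- which(!is.na(counts))
  if (!length(V)) stop("cannot initialize the latent trajectory: no observed counts")
  n0 <- approx(x = V, y = counts[V], xout = seq_len(Tn), rule = 2)$y
  pmax(1, round(n0))
}

# Crude least-squares starting point for beta: regress the realized log
# growth rates of the (gap-filled) count series on the effective design.
# Gives each chain a data-informed centre and a per-parameter scale for
# the jitter and the pre-adaptation proposal; the sampler remains valid
# regardless of its quality.
init_beta_ls <- function(n0, X, spec, prior_sd) {
  Tn <- length(n0)
  mult <- spec_columns(spec)$mult_by_n
  Xe <- X[2:Tn, , drop = FALSE]
  Xe[, mult] <- Xe[, mult, drop = FALSE] * n0[1:(Tn - 1)]
  y <- log(n0[2:Tn] / n0[1:(Tn - 1)])
  fit <- tryCatch(stats::lm.fit(Xe, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(list(center = rep(0, ncol(X)), scale = 0.1 * prior_sd))
  }
  dfres <- max(1, length(y) - ncol(Xe))
  sigma2 <- sum(fit$residuals^2) / dfres
  XtX <- crossprod(Xe)
  se <- tryCatch(sqrt(diag(solve(XtX)) * sigma2), error = function(e) NULL)
  if (is.null(se) || any(!is.finite(se))) se <- 0.1 * prior_sd
  list(center = unname(fit$coefficients),
       scale = pmin(pmax(se, 1e-8 * prior_sd), prior_sd))
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Samples the joint posterior of the growth parameters `beta`, the
#' detection probability `p` and the latent abundances `n_1..n_T` given a
#' count series (NA = unobserved year) and a design matrix. Chains start
#' from overdispersed initial values (latent trajectory at the observed
#' counts, linearly interpolated across gaps; `beta` centred on a crude
#' log-growth least-squares estimate with chain-specific jitter at the
#' scale of its standard errors; `p` near 0.5) and adapt their proposal
#' scales during burn-in only.
#'
#' @param counts integer count vector with `NA` for unobserved years, or a
#'   `guanaco_data` object (its `counts` are used).
#' @param X design matrix from [build_design()].
#' @param spec growth [model_spec()].
#' @param priors an [ssm_priors()]; defaults to `ssm_priors(spec)`.
#' @param config an [mcmc_config()].
#' @param p_method `"metropolis_logit"` (default; Metropolis on the logit
#'   scale targeting the exact conditional of `p`) or `"pseudo_conjugate"`
#'   (Beta draw with the NB sizes held at the current `p`).
#' @param update_beta,update_p,update_latent disable blocks to sample
#'   conditional distributions (used by validation tests).
#' @param init optional list overriding initial values: any of `beta`,
#'   `p`, `latent`.
#' @return A `ssm_samples` object: arrays `beta` (draws x k x chains), `p`
#'   (draws x chains), `latent` (draws x T x chains), `log_post`, per-chain
#'   acceptance rates, plus the spec, design, counts, priors and config.
#' @export
run_mcmc <- function(counts, X, spec, priors = NULL, config = mcmc_config(),
                     p_method = c("metropolis_logit", "pseudo_conjugate"),
                     update_beta = TRUE, update_p = TRUE, update_latent = TRUE,
                     init = NULL) {
  p_method <- match.arg(p_method)
  counts <- .get_counts(counts)
  stopifnot(inherits(spec, "ssm_spec"), nrow(X) == length(counts),
            ncol(X) == spec$k)
  if (is.null(priors)) priors <- ssm_priors(spec)
  Tn <- length(counts)
  k <- spec$k
  M <- n_retained(config)
  if (M < 1) stop("configuration retains no draws")
  mult <- spec_columns(spec)$mult_by_n
  observed <- as.integer(!is.na(counts))
  prior_sd <- sqrt(diag(priors$beta_cov))

  lat0_base <- if (!is.null(init$latent)) init$latent else init_latent(counts)
  ls0 <- init_beta_ls(lat0_base, X, spec, prior_sd)

  beta_arr <- array(NA_real_, c(M, k, config$n_chains),
                    dimnames = list(NULL, spec_columns(spec)$names, NULL))
  p_mat <- matrix(NA_real_, M, config$n_chains)
  lat_arr <- array(NA_real_, c(M, Tn, config$n_chains))
  lp_mat <- matrix(NA_real_, M, config$n_chains)
  accept <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * (ch - 1L))
    beta0 <- if (!is.null(init$beta)) init$beta else
      ls0$center + rnorm(k, 0, ls0$scale)
    p0 <- if (!is.null(init$p)) init$p else min(max(0.5 + runif(1, -0.2, 0.3), 0.05), 0.95)
    lat0 <- lat0_base

    # fail early, naming the year, if the starting state has no support
    for (t in 2:Tn) {
      lp_t <- tryCatch(
        proc_loglik(lat0[t], growth_expectation(lat0[t - 1], beta0, X[t, ], spec)),
        error = function(e) -Inf
      )
      if (!is.finite(lp_t)) {
        stop("non-finite log posterior at initialization, first offending year index: ", t)
      }
    }

    res <- .mcmc_chain(
      as.numeric(ifelse(is.na(counts), 0, counts)), observed,
      X, as.integer(mult),
      as.numeric(priors$beta_mean), priors$beta_cov, priors$s1, priors$s2,
      as.numeric(beta0), p0, as.numeric(lat0),
      config$n_iter, config$burn_in, config$thin,
      update_beta, update_p, update_latent,
      if (p_method == "metropolis_logit") 0L else 1L,
      config$target_accept, 0.4, config$adapt_window,
      as.numeric(ls0$scale)
    )
    beta_arr[, , ch] <- res$beta
    p_mat[, ch] <- res$p
    lat_arr[, , ch] <- res$latent
    lp_mat[, ch] <- res$log_post
    accept[[ch]] <- res$accept
  }

  structure(
    list(beta = beta_arr, p = p_mat, latent = lat_arr, log_post = lp_mat,
         accept = accept, spec = spec, X = X, counts = counts,
         priors = priors, config = config, p_method = p_method),
    class = "ssm_samples"
  )
}

#' @export
print.ssm_samples <- function(x, ...) {
  cat("Posterior samples for model '", x$spec$label, "': ",
      dim(x$beta)[1], " draws x ", dim(x$beta)[3], " chains\n", sep = "")
  invisible(x)
}

# Pool draws across chains into a plain matrix: (M * n_chains) x (k + 1 + T).
pool_draws <- function(samples) {
  M <- dim(samples$beta)[1]
  k <- dim(samples$beta)[2]
  nc <- dim(samples$beta)[3]
  beta <- do.call(rbind, lapply(seq_len(nc), function(ch) samples$beta[, , ch, drop = FALSE][, , 1, drop = TRUE]))
  if (k == 1L) beta <- matrix(beta, ncol = 1L, dimnames = list(NULL, dimnames(samples$beta)[[2]]))
  latent <- do.call(rbind, lapply(seq_len(nc), function(ch) samples$latent[, , ch]))
  list(beta = beta, p = as.vector(samples$p), latent = latent,
       log_post = as.vector(samples$log_post))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the split-free multi-chain R-hat for every scalar parameter:
#' with `m` retained draws per chain, between-chain variance `B` and
#' within-chain variance `W`, `R-hat = sqrt(((m-1)/m * W + B/m) / W)`.
#' Values near 1 indicate the chains have mixed.
#'
#' @param samples a `ssm_samples` object (>= 2 chains, >= 10 draws each),
#'   or a numeric matrix of draws by chains for a single parameter.
#' @param include_latent also report R-hat for each latent abundance.
#' @return Named numeric vector of R-hat values.
#' @export
psrf <- function(samples, include_latent = FALSE) {
  if (is.matrix(samples)) return(c(psrf_matrix(samples)))
  stopifnot(inherits(samples, "ssm_samples"))
  nc <- dim(samples$beta)[3]
  M <- dim(samples$beta)[1]
  if (nc < 2) stop("potential scale reduction needs at least 2 chains")
  if (M < 10) stop("potential scale reduction needs at least 10 retained draws per chain")
  k <- dim(samples$beta)[2]
  out <- c(
    vapply(seq_len(k), function(j) psrf_matrix(samples$beta[, j, ]), numeric(1)),
    p = psrf_matrix(samples$p)
  )
  names(out)[seq_len(k)] <- dimnames(samples$beta)[[2]]
  if (include_latent) {
    Tn <- dim(samples$latent)[2]
    lat <- vapply(seq_len(Tn), function(t) psrf_matrix(samples$latent[, t, ]), numeric(1))
    names(lat) <- paste0("n_", seq_len(Tn))
    out <- c(out, lat)
  }
  out
}

psrf_matrix <- function(draws) {
  m <- nrow(draws)
  W <- mean(apply(draws, 2, var))
  B <- m * var(colMeans(draws))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Posterior summary table for a fitted model
#'
#' @param object a `ssm_samples` object.
#' @param ... unused.
#' @return A data.frame with mean, sd and 2.5/50/97.5 percentiles for each
#'   growth parameter and the detection probability.
#' @export
summary.ssm_samples <- function(object, ...) {
  pool <- pool_draws(object)
  draws <- cbind(pool$beta, p = pool$p)
  data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    q2.5 = apply(draws, 2, quantile, 0.025),
    q50 = apply(draws, 2, quantile, 0.5),
    q97.5 = apply(draws, 2, quantile, 0.975),
    row.names = NULL
  )
}
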