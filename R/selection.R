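# Posterior-predictive simulation and Gelfand-Ghosh predictive-loss
# scoring: G (error sum of squares of the predictive means), P (total
# predictive variance), D = G + P; the candidate with the lowest D wins.

# The 27 candidate growth models of the full comparison, in their
# published comparison order (term sets over DD, Temp, Precip, Sheep and
# the two covariate-by-density interactions).
.MODEL_LABELS_RAW <- c(
  "DD + Temp + Sheep",
  "DD + Sheep + Temp*DD",
  "DD + Temp + Precip + Sheep",
  "DD + Sheep + Temp*DD + Precip*DD",
  "DD + Temp*DD",
  "DD + Temp",
  "DD + Temp + Precip",
  "DD + Temp*DD + Precip*DD",
  "DD + Sheep + Precip*DD",
  "DD + Sheep",
  "DD + Precip + Sheep",
  "DD + Precip",
  "DD + Precip*DD",
  "DD",
  "Temp",
  "Precip",
  "Sheep",
  "Temp*DD",
  "Precip*DD",
  "Temp + Precip",
  "Temp + Sheep",
  "Precip + Sheep",
  "Temp*DD + Precip*DD",
  "Sheep + Temp*DD",
  "Sheep + Precip*DD",
  "Sheep + Temp*DD + Precip*DD",
  "Temp + Precip + Sheep"
)

#' Enumerate the 27 candidate growth models
#'
#' All combinations compared in the full analysis: density dependence,
#' the three covariates and the two covariate-by-density interactions
#' (interaction terms appear with and without the DD main effect; the
#' plain intercept-only exponential model is available separately under
#' the label `"Null"` but is not part of this table).
#'
#' @return Named list of 27 [model_spec()] objects, names = labels.
#' @export
enumerate_models <- function() {
  labels <- gsub("*", paste0(" ", .TIMES, " "), .MODEL_LABELS_RAW, fixed = TRUE)
  specs <- lapply(labels, spec_from_label)
  names(specs) <- labels
  specs
}

#' Posterior-predictive count draws
#'
#' For each of `M` retained posterior draws `(beta^m, p^m, n^m)` (pooled
#' across chains; resampled with replacement if `M` exceeds the pool),
#' simulates a replicate count `o'_t ~ NegBin(mean n_t^m, size
#' n_t^m/(1/p^m - 1))` for every observed year.
#'
#' @param samples a `ssm_samples` object.
#' @param counts the observed counts (NA = unobserved) or a dataset.
#' @param M number of predictive draws (default 10,000).
#' @param seed optional integer seed.
#' @return A list of class `ssm_predictive`: `draws` (M x |V| matrix),
#'   `years_idx` (indices of observed years), `mean` and `q2.5/q50/q97.5`
#'   per observed year.
#' @export
posterior_predict <- function(samples, counts, M = 10000L, seed = NULL) {
  stopifnot(inherits(samples, "ssm_samples"))
  counts <- .get_counts(counts)
  V <- which(!is.na(counts))
  if (!length(V)) stop("no observed years to predict")
  pool <- pool_draws(samples)
  n_pool <- length(pool$p)
  if (!n_pool) stop("empty posterior sample")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (M <= n_pool) sample.int(n_pool, M) else sample.int(n_pool, M, replace = TRUE)
  lat <- pool$latent[idx, V, drop = FALSE]
  p <- pool$p[idx]
  draws <- matrix(rnbinom(length(lat), size = lat / (1 / p - 1), mu = lat),
                  nrow = M, ncol = length(V))
  structure(
    list(draws = draws, years_idx = V,
         mean = colMeans(draws),
         q2.5 = apply(draws, 2, quantile, 0.025),
         q50 = apply(draws, 2, quantile, 0.5),
         q97.5 = apply(draws, 2, quantile, 0.975)),
    class = "ssm_predictive"
  )
}

#' Gelfand-Ghosh predictive loss
#'
#' `G = sum_t (o_t - mean_m o'_t)^2` over observed years (goodness of
#' fit), `P = sum_t var_m(o'_t)` (penalty: total predictive variance,
#' unbiased M-1 divisor), and `D = G + P`; the selected model minimizes D.
#'
#' @param observed counts at the observed years (no NA), aligned with the
#'   predictive draw columns.
#' @param draws predictive draw matrix (M x |V|) or a `ssm_predictive`.
#' @return Named numeric vector `c(G, P, D)`.
#' @export
predictive_loss <- function(observed, draws) {
  if (inherits(draws, "ssm_predictive")) draws <- draws$draws
  if (!is.matrix(draws) || nrow(draws) < 1L) stop("need a nonempty predictive draw matrix")
  if (nrow(draws) < 2L) stop("need at least 2 predictive draws to measure variance")
  observed <- as.numeric(observed)
  if (anyNA(observed)) stop("observed counts must be complete over the predicted years")
  if (length(observed) != ncol(draws)) stop("observed length must match draw columns")
  G <- sum((observed - colMeans(draws))^2)
  P <- sum(apply(draws, 2, var))
  c(G = G, P = P, D = G + P)
}

#' Fit a set of candidate models and score them
#'
#' Runs the sampler for each candidate specification (per-model seed =
#' `config$seed + model index`), draws posterior predictions and computes
#' the predictive loss for each, returning the comparison table sorted by
#' ascending D.
#'
#' @param data a `guanaco_data` object.
#' @param specs list of [model_spec()] objects (e.g. [enumerate_models()]),
#'   or a character vector of labels.
#' @param config an [mcmc_config()].
#' @param M predictive draws per model.
#' @param anomaly,lag covariate preparation options (see
#'   [prepare_covariates()] and [build_design()]).
#' @param keep_samples keep each model's `ssm_samples` (memory-heavy for
#'   large candidate sets).
#' @param p_method passed to [run_mcmc()].
#' @return A list of class `ssm_selection`: `table` (data.frame `model`,
#'   `G`, `P`, `D` sorted ascending by D), and `samples` (named list, only
#'   if `keep_samples`).
#' @export
fit_models <- function(data, specs = enumerate_models(), config = mcmc_config(),
                       M = 10000L, anomaly = "standardized", lag = 1L,
                       keep_samples = FALSE, p_method = "metropolis_logit") {
  stopifnot(inherits(data, "guanaco_data"))
  if (is.character(specs)) specs <- setNames(lapply(specs, spec_from_label), specs)
  covs <- prepare_covariates(data, anomaly = anomaly)
  Tn <- length(data$years)
  V <- which(!is.na(data$counts))
  obs <- data$counts[V]
  rows <- vector("list", length(specs))
  kept <- if (keep_samples) vector("list", length(specs)) else NULL
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    X <- build_design(sp, covs, Tn, lag = lag)
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- run_mcmc(data$counts, X, sp, config = cfg, p_method = p_method)
    pred <- posterior_predict(fit, data$counts, M = M, seed = cfg$seed)
    gpd <- predictive_loss(obs, pred)
    rows[[i]] <- data.frame(model = sp$label, G = gpd[["G"]], P = gpd[["P"]],
                            D = gpd[["D"]])
    if (keep_samples) kept[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$D), ]
  rownames(tab) <- NULL
  if (keep_samples) names(kept) <- vapply(specs, `[[`, "", "label")
  structure(list(table = tab, samples = kept), class = "ssm_selection")
}

#' @export
print.ssm_selection <- function(x, ...) {
  cat("Predictive-loss model comparison (", nrow(x$table), " models):\n", sep = "")
  print(x$table, digits = 6)
  invisible(x)
}

#' Pick the winning model from a selection table
#'
#' Returns the row with the lowest predictive loss D; exact ties are
#' broken by fewer model terms, then label order.
#'
#' @param table a `ssm_selection` object or its `table` data.frame.
#' @return The winning [model_spec()].
#' @export
select_best <- function(table) {
  if (inherits(table, "ssm_selection")) table <- table$table
  if (!is.data.frame(table) || !nrow(table)) stop("empty selection table")
  cand <- table[table$D == min(table$D), , drop = FALSE]
  if (nrow(cand) > 1L) {
    nterms <- vapply(cand$model, function(l) spec_from_label(l)$k, integer(1))
    cand <- cand[order(nterms, cand$model), , drop = FALSE]
  }
  spec_from_label(cand$model[1])
}
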