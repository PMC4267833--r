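# End-to-end orchestration: read -> covariates -> fit candidates ->
# predictive-loss selection -> carrying capacity and growth-rate curves ->
# report files. Everything is deterministic given the base seed.

#' Read a yearly count/covariate dataset from CSV
#'
#' Expected header: `year,count,winter_temp,precip,sheep`, one row per
#' consecutive year; empty `count` cells mark unsurveyed years and empty
#' `sheep` cells mark years between sheep knots. Weather columns must be
#' complete.
#'
#' @param path CSV file path.
#' @return A `guanaco_data` object.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "count", "winter_temp", "precip", "sheep")
  if (!identical(names(df), need)) {
    stop("dataset header must be exactly '", paste(need, collapse = ","), "'")
  }
  if (anyDuplicated(df$year)) {
    stop("duplicated year in dataset: ", df$year[duplicated(df$year)][1])
  }
  if (is.unsorted(df$year)) stop("years must be increasing")
  if (!all(diff(df$year) == 1)) {
    gap <- df$year[which(diff(df$year) != 1)[1]]
    stop("years must be consecutive; gap after ", gap)
  }
  cnt <- df$count
  if (!all(is.na(cnt) | (is.finite(cnt) & cnt == floor(cnt) & cnt >= 0))) {
    stop("counts must be nonnegative integers (or empty)")
  }
  if (anyNA(df$winter_temp) || anyNA(df$precip)) {
    stop("weather columns must be complete")
  }
  knots <- which(!is.na(df$sheep))
  new_dataset(df$year, cnt, df$winter_temp, df$precip,
              df$year[knots], df$sheep[knots])
}

#' Write a dataset (and optional truth sidecar) to CSV
#'
#' Inverse of [read_dataset()]. For synthetic data, the stored truth
#' (latent trajectory and generating parameters) is written alongside as
#' `<path base>_truth.csv`.
#'
#' @param data a `guanaco_data` object.
#' @param path output CSV path.
#' @param truth write the truth sidecar if the dataset carries one.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, truth = TRUE) {
  stopifnot(inherits(data, "guanaco_data"))
  sheep <- rep(NA_real_, length(data$years))
  sheep[match(data$sheep_year, data$years)] <- data$sheep_count
  df <- data.frame(year = data$years, count = data$counts,
                   winter_temp = data$winter_temp, precip = data$precip,
                   sheep = sheep)
  write.csv(df, path, row.names = FALSE, na = "")
  if (truth && !is.null(data$truth)) {
    tr <- data$truth
    side <- data.frame(year = data$years, latent = tr$latent)
    write.csv(side, sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Analysis configuration
#'
#' @param input a `guanaco_data` object or path to a dataset CSV.
#' @param models `"all"` (the 27-model table), or a character vector of
#'   model labels (may include `"Null"`).
#' @param mcmc an [mcmc_config()]; its seed is the base seed (model `i`
#'   is fitted with `seed + i`).
#' @param anomaly,lag covariate preparation options.
#' @param p_method detection-probability sampler, see [run_mcmc()].
#' @param M predictive draws per model for the selection step.
#' @param k_years calendar years over which covariates are averaged for
#'   the carrying-capacity estimate; default the last six observed years.
#' @param sheep_counterfactual optional sheep head count; K is re-computed
#'   with the sheep covariate mean replaced by this value (rescaled by the
#'   same series maximum), all else unchanged.
#' @param outdir optional output directory for [write_outputs()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input, models = "all", mcmc = mcmc_config(),
                            anomaly = "standardized", lag = 1L,
                            p_method = "metropolis_logit", M = 10000L,
                            k_years = NULL, sheep_counterfactual = NULL,
                            outdir = NULL) {
  structure(
    list(input = input, models = models, mcmc = mcmc, anomaly = anomaly,
         lag = as.integer(lag), p_method = p_method, M = as.integer(M),
         k_years = k_years, sheep_counterfactual = sheep_counterfactual,
         outdir = outdir),
    class = "analysis_config"
  )
}

# Covariate means over an interval of calendar years, on the transformed
# scale (the scale the growth parameters act on). Used for K.
covariate_means <- function(covs, years, k_years, spec) {
  idx <- match(k_years, years)
  if (anyNA(idx)) stop("K interval years outside the dataset span")
  need <- union(spec$covariates, spec$interactions)
  vapply(need, function(cv) mean(covs[[cv]][idx]), numeric(1))
}

# Posterior draws of K from pooled beta draws; draws without a stable
# equilibrium (nonnegative DD denominator) are dropped with a count kept.
k_posterior <- function(pool_beta, spec, xbar) {
  ks <- apply(pool_beta, 1, function(b) {
    tryCatch(carrying_capacity(b, spec, xbar), error = function(e) NA_real_)
  })
  ok <- ks[is.finite(ks)]
  list(draws = ok, mean = mean(ok), sd = sd(ok),
       q2.5 = quantile(ok, 0.025, names = FALSE),
       q97.5 = quantile(ok, 0.975, names = FALSE),
       n_dropped = sum(!is.finite(ks)))
}

#' Run the full analysis
#'
#' Reads the data, prepares covariates, fits every candidate model,
#' selects the winner by predictive loss, summarizes its posterior, and
#' derives carrying-capacity estimates (for the configured interval and,
#' optionally, under a counterfactual sheep abundance) plus the fitted
#' latent trajectory with 95% credible bands and convergence diagnostics.
#'
#' @param config an [analysis_config()].
#' @return A list of class `analysis_report`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  data <- config$input
  if (is.character(data)) data <- read_dataset(data)
  stopifnot(inherits(data, "guanaco_data"))
  covs <- prepare_covariates(data, anomaly = config$anomaly)
  Tn <- length(data$years)

  specs <- if (identical(config$models, "all")) enumerate_models() else
    setNames(lapply(config$models, spec_from_label), config$models)

  sel <- tryCatch(
    fit_models(data, specs, config = config$mcmc, M = config$M,
               anomaly = config$anomaly, lag = config$lag,
               keep_samples = TRUE, p_method = config$p_method),
    error = function(e) stop("model fitting stage failed: ", conditionMessage(e))
  )
  best <- select_best(sel)
  best_fit <- sel$samples[[best$label]]
  pool <- pool_draws(best_fit)

  # carrying capacity over the configured interval (default: last 6
  # observed years), from the winning model's posterior
  obs_years <- data$years[!is.na(data$counts)]
  k_years <- if (is.null(config$k_years)) utils::tail(obs_years, 6) else config$k_years
  K <- NULL
  K_counterfactual <- NULL
  if (best$has_dd || length(best$interactions)) {
    xbar <- covariate_means(covs, data$years, k_years, best)
    K <- tryCatch(c(k_posterior(pool$beta, best, xbar), list(years = k_years)),
                  error = function(e) NULL)
    if (!is.null(config$sheep_counterfactual) && "Sheep" %in% names(xbar)) {
      xbar2 <- xbar
      xbar2[["Sheep"]] <- config$sheep_counterfactual / attr(covs$Sheep, "scale")
      K_counterfactual <- c(k_posterior(pool$beta, best, xbar2),
                            list(sheep = config$sheep_counterfactual))
    }
  }

  # fitted latent trajectory with 95% credible band, plus the posterior
  # predictive band for the counts at observed years
  traj <- data.frame(
    year = data$years,
    count = data$counts,
    n_mean = apply(pool$latent, 2, mean),
    n_q2.5 = apply(pool$latent, 2, quantile, 0.025),
    n_q97.5 = apply(pool$latent, 2, quantile, 0.975)
  )
  pred <- posterior_predict(best_fit, data$counts, M = config$M,
                            seed = config$mcmc$seed)

  diag_tab <- data.frame(parameter = names(psrf(best_fit)), rhat = psrf(best_fit),
                         row.names = NULL)
  acc <- colMeans(do.call(rbind, lapply(best_fit$accept, function(a)
    unlist(a, use.names = TRUE))))

  structure(
    list(selection = sel$table, best = best, best_summary = summary(best_fit),
         best_fit = best_fit, K = K, K_counterfactual = K_counterfactual,
         trajectory = traj, predictive = pred, diagnostics = diag_tab,
         acceptance = acc, config = config, data = data),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Selected model:", x$best$label, "\n")
  if (!is.null(x$K)) {
    cat(sprintf("K over %d-%d: %.0f (sd %.0f, 95%% CI %.0f-%.0f)\n",
                min(x$K$years), max(x$K$years), x$K$mean, x$K$sd,
                x$K$q2.5, x$K$q97.5))
  }
  if (!is.null(x$K_counterfactual)) {
    cat(sprintf("K at %s sheep: %.0f (sd %.0f)\n",
                format(x$K_counterfactual$sheep, big.mark = ","),
                x$K_counterfactual$mean, x$K_counterfactual$sd))
  }
  cat("max R-hat:", round(max(x$diagnostics$rhat), 3), "\n")
  invisible(x)
}

#' Posterior growth-rate curve along one covariate
#'
#' Evaluates the expected per-capita growth rate `lambda = exp(b0 + b1 K +
#' b_c g + ...)` on a grid `g` of one covariate, holding the other
#' covariates at `fixed` values (default 0, the covariate mean on the
#' anomaly scale) and the abundance at each draw's carrying capacity (or
#' a supplied fixed abundance for models without density dependence),
#' with 95% credible bands.
#'
#' @param samples a fitted `ssm_samples`.
#' @param covariate which covariate to vary (must be in the model).
#' @param grid numeric grid of covariate values (transformed scale).
#' @param fixed named list/vector of values for the other covariates.
#' @param abundance optional fixed abundance overriding the per-draw K.
#' @return data.frame `x`, `lambda_mean`, `lambda_q2.5`, `lambda_q97.5`.
#' @export
growth_rate_curve <- function(samples, covariate, grid, fixed = NULL,
                              abundance = NULL) {
  stopifnot(inherits(samples, "ssm_samples"))
  spec <- samples$spec
  if (!covariate %in% union(spec$covariates, spec$interactions)) {
    stop("covariate '", covariate, "' is not in model '", spec$label, "'")
  }
  if (any(!is.finite(grid))) stop("grid must be finite")
  cols <- spec_columns(spec)
  pool <- pool_draws(samples)
  B <- pool$beta
  other <- setdiff(union(spec$covariates, spec$interactions), covariate)
  fx <- setNames(rep(0, length(other)), other)
  if (length(fixed)) fx[names(fixed)] <- unlist(fixed)

  # abundance entering the DD terms: per-draw K (at the fixed covariate
  # values, with the varied covariate at its mean, 0) unless overridden
  n_eval <- if (!is.null(abundance)) rep(abundance, nrow(B)) else {
    if (!spec$has_dd && !length(spec$interactions)) {
      stop("models without density dependence need a fixed 'abundance'")
    }
    xb <- c(fx, setNames(0, covariate))
    apply(B, 1, function(b) tryCatch(carrying_capacity(b, spec, xb),
                                     error = function(e) NA_real_))
  }
  keep <- is.finite(n_eval)
  B <- B[keep, , drop = FALSE]
  n_eval <- n_eval[keep]
  if (!nrow(B)) stop("no posterior draws with a stable equilibrium")

  out <- lapply(grid, function(g) {
    xrow <- setNames(rep(1, spec$k), cols$names)
    for (cv in spec$covariates) xrow[cv] <- if (cv == covariate) g else fx[[cv]]
    for (cv in spec$interactions) {
      xrow[paste0(cv, ":DD")] <- if (cv == covariate) g else fx[[cv]]
    }
    x_eff <- matrix(rep(xrow, each = nrow(B)), nrow = nrow(B))
    x_eff[, cols$mult_by_n] <- x_eff[, cols$mult_by_n, drop = FALSE] * n_eval
    lam <- exp(rowSums(B * x_eff))
    c(mean(lam), quantile(lam, c(0.025, 0.975), names = FALSE))
  })
  out <- do.call(rbind, out)
  data.frame(x = grid, lambda_mean = out[, 1], lambda_q2.5 = out[, 2],
             lambda_q97.5 = out[, 3])
}

#' Write report files
#'
#' Writes the selection table, best-model posterior draws and summary,
#' fitted trajectory, diagnostics and a plain-text report (with the full
#' configuration echo and seeds) under `directory`, creating it if
#' needed.
#'
#' @param report an `analysis_report`.
#' @param directory output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(report, directory) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    fp <- file.path(directory, name)
    write.csv(df, fp, row.names = FALSE)
    paths <<- c(paths, fp)
  }
  wr(report$selection, "selection.csv")
  pool <- pool_draws(report$best_fit)
  draws <- data.frame(
    chain = rep(seq_len(dim(report$best_fit$beta)[3]),
                each = dim(report$best_fit$beta)[1]),
    pool$beta, p = pool$p, check.names = FALSE
  )
  wr(draws, "posterior_beta_p.csv")
  wr(data.frame(chain = draws$chain, pool$latent), "posterior_latent.csv")
  wr(report$best_summary, "posterior_summary.csv")
  wr(report$trajectory, "trajectory.csv")
  wr(report$diagnostics, "diagnostics.csv")

  rp <- file.path(directory, "report.txt")
  con <- file(rp, "w")
  on.exit(close(con))
  cfg <- report$config
  writeLines(c(
    "Guanaco state-space analysis report",
    "===================================",
    paste0("models: ", paste(report$selection$model, collapse = " | ")),
    paste0("selected: ", report$best$label),
    paste0("base seed: ", cfg$mcmc$seed,
           "; chains: ", cfg$mcmc$n_chains,
           "; iterations: ", cfg$mcmc$n_iter,
           "; burn-in: ", cfg$mcmc$burn_in,
           "; thin: ", cfg$mcmc$thin),
    paste0("anomaly: ", cfg$anomaly, "; lag: ", cfg$lag,
           "; p sampler: ", cfg$p_method, "; predictive draws M: ", cfg$M),
    if (!is.null(report$K)) sprintf(
      "K (%d-%d): mean %.1f sd %.1f CI [%.1f, %.1f]",
      min(report$K$years), max(report$K$years), report$K$mean, report$K$sd,
      report$K$q2.5, report$K$q97.5),
    if (!is.null(report$K_counterfactual)) sprintf(
      "K at %.0f sheep: mean %.1f sd %.1f",
      report$K_counterfactual$sheep, report$K_counterfactual$mean,
      report$K_counterfactual$sd),
    paste0("max R-hat: ", format(max(report$diagnostics$rhat), digits = 4)),
    paste0("acceptance: ", paste(names(report$acceptance), "=",
                                 round(report$acceptance, 3), collapse = ", "))
  ), con)
  paths <- c(paths, rp)
  invisible(paths)
}
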