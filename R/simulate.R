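# Synthetic data with the statistical structure the analysis assumes:
# autocorrelated weather, a sparse smoothly-varying sheep series, and a
# latent Poisson/Ricker trajectory observed through negative-binomial
# counts with detection probability p.

#' Simulate an autocorrelated weather series
#'
#' Stationary Gaussian AR(1): `v_t = mean + phi (v_{t-1} - mean) + e_t`
#' with innovation variance chosen so the marginal standard deviation is
#' `sd` (the first value is drawn from the stationary distribution).
#'
#' @param T series length in years (>= 3).
#' @param persistence lag-1 autocorrelation `phi` in `[0, 1)`.
#' @param mean,sd marginal mean and standard deviation.
#' @param seed optional integer seed (calls `set.seed`).
#' @return Numeric vector of length `T`.
#' @export
simulate_weather <- function(T, persistence = 0.3, mean = 0, sd = 1, seed = NULL) {
  stopifnot(T >= 3)
  if (persistence < 0 || persistence >= 1) stop("persistence must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  v <- numeric(T)
  v[1] <- rnorm(1, mean, sd)
  innov_sd <- sd * sqrt(1 - persistence^2)
  for (t in 2:T) {
    v[t] <- mean + persistence * (v[t - 1] - mean) + rnorm(1, 0, innov_sd)
  }
  v
}

#' Simulate a sparse sheep count series
#'
#' Draws `n_knots` positive sheep abundances at years spread evenly across
#' the study span, varying smoothly (a logistic-transformed random walk)
#' within `level_range`. Defaults emulate a 2000 km2 ranch holding 11-23
#' sheep per km2: 8 knots between 22,000 and 46,000 head.
#'
#' @param T study length in years.
#' @param n_knots number of observed years (2 to `T`).
#' @param level_range numeric length-2: bounds for the sheep abundance.
#' @param seed optional integer seed.
#' @return A data.frame with columns `year` (indices in `1:T`) and `count`.
#' @export
simulate_sheep <- function(T, n_knots = 8, level_range = c(22000, 46000), seed = NULL) {
  stopifnot(T >= 2)
  if (n_knots < 2) stop("need at least 2 sheep knots")
  if (n_knots > T) stop("more knots than years")
  if (!is.null(seed)) set.seed(seed)
  years <- unique(round(seq(1, T, length.out = n_knots)))
  # smooth variation inside the range: random walk squashed to (0, 1)
  walk <- cumsum(rnorm(length(years), 0, 0.8))
  u <- stats::plogis(walk - walk[1] + rnorm(1, 0, 1))
  counts <- level_range[1] + (level_range[2] - level_range[1]) * u
  data.frame(year = years, count = counts)
}

#' Simulate a latent trajectory and its observed counts
#'
#' Generative pass through the hierarchical model: `n_1 = n0`, then
#' `n_t ~ Poisson(lambda_t)` with `lambda_t` from [growth_expectation()],
#' and counts `o_t ~ NegBin(mean n_t, size n_t/(1/p - 1))` (exact Poisson
#' when `p = 1`). Counts at `missing_years` are masked to `NA`. If the
#' latent trajectory is absorbed at zero the draw is retried with a fresh
#' sub-seed up to 10 times before failing.
#'
#' @param params list with `beta` (length-k growth parameters), `p`
#'   (detection, in (0, 1]), `n0` (initial abundance), `T` (years),
#'   `missing_years` (integer indices, possibly empty) and optional `seed`.
#' @param X design matrix from [build_design()] with at least `T` rows.
#' @param spec the growth [model_spec()] the parameters refer to.
#' @return A list of class `ssm_sim` with `counts` (NA at masked years),
#'   `latent`, `params`, `spec` and the number of `retries` used.
#' @export
simulate_trajectory <- function(params, X, spec) {
  stopifnot(inherits(spec, "ssm_spec"))
  p <- params$p
  Tn <- params$T
  if (is.null(p) || p <= 0 || p > 1) stop("detection p must lie in (0, 1]")
  if (is.null(params$n0) || params$n0 < 1) stop("n0 must be >= 1")
  if (is.null(Tn) || Tn < 3) stop("T must be >= 3")
  if (length(params$beta) != spec$k) stop("beta must have length k = ", spec$k)
  if (nrow(X) < Tn) stop("design matrix has fewer than T rows")
  missing_years <- params$missing_years
  if (any(missing_years < 1 | missing_years > Tn)) stop("missing_years out of range")

  seed <- if (is.null(params$seed)) NULL else params$seed
  for (attempt in 0:10) {
    if (attempt == 10) stop("trajectory absorbed at zero in 10 consecutive attempts")
    if (!is.null(seed)) set.seed(seed + 1009L * attempt)
    n <- numeric(Tn)
    n[1] <- round(params$n0)
    ok <- TRUE
    for (t in 2:Tn) {
      lam <- growth_expectation(n[t - 1], params$beta, X[t, ], spec)
      n[t] <- rpois(1, lam)
      if (n[t] < 1) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  if (attempt > 0) message("trajectory retried ", attempt, " time(s) after latent extinction")
  o <- if (p == 1) rpois(Tn, n) else rnbinom(Tn, size = n / (1 / p - 1), mu = n)
  o[missing_years] <- NA_integer_
  structure(
    list(counts = as.integer(o), latent = as.integer(n), params = params,
         spec = spec, retries = attempt),
    class = "ssm_sim"
  )
}

# Container for a complete synthetic study: counts + raw covariate series
# + stored truth. Mirrors the CSV schema read_dataset() consumes.
new_dataset <- function(years, counts, winter_temp, precip, sheep_year,
                        sheep_count, truth = NULL) {
  structure(
    list(
      years = as.integer(years), counts = as.integer(counts),
      winter_temp = as.numeric(winter_temp), precip = as.numeric(precip),
      sheep_year = as.integer(sheep_year), sheep_count = as.numeric(sheep_count),
      truth = truth
    ),
    class = "guanaco_data"
  )
}

#' @export
print.guanaco_data <- function(x, ...) {
  Tn <- length(x$years)
  cat("Guanaco count dataset: ", Tn, " years (", x$years[1], "-", x$years[Tn],
      "), ", sum(!is.na(x$counts)), " observed counts, ",
      length(x$sheep_year), " sheep knots",
      if (!is.null(x$truth)) " [synthetic, truth stored]", "\n", sep = "")
  invisible(x)
}

#' Prepare model covariates from a dataset
#'
#' Transforms the raw series into what the growth model consumes: weather
#' anomalies ([compute_anomaly()]) for winter temperature and annual
#' precipitation, and the sheep series interpolated to every year
#' ([interpolate_linear()]) then rescaled by its maximum
#' ([rescale_to_max()]).
#'
#' @param data a `guanaco_data` object.
#' @param anomaly `"standardized"` or `"centered"`, passed to
#'   [compute_anomaly()].
#' @return Named list with complete series `Temp`, `Precip`, `Sheep`; the
#'   `Sheep` element keeps the `scale` attribute (the interpolated series
#'   maximum) used to rescale counterfactual sheep numbers.
#' @export
prepare_covariates <- function(data, anomaly = c("standardized", "centered")) {
  stopifnot(inherits(data, "guanaco_data"))
  anomaly <- match.arg(anomaly)
  sheep_full <- interpolate_linear(data$sheep_year, data$sheep_count, data$years)
  list(
    Temp = compute_anomaly(data$winter_temp, method = anomaly),
    Precip = compute_anomaly(data$precip, method = anomaly),
    Sheep = rescale_to_max(sheep_full)
  )
}

#' Generate a named synthetic study scenario
#'
#' Fully populated synthetic datasets used throughout the tests and the
#' calibration experiments:
#' \describe{
#'   \item{`paper_like`}{36 years; counts growing from a few thousand
#'     toward fluctuation around an equilibrium near 45,000; growth model
#'     DD + Temp + Sheep with intrinsic rate 0.18, temperature effect
#'     +0.05 per sd anomaly, sheep effect -0.05 per rescaled unit (so the
#'     realized net growth rate stays near 0.14/yr and the series actually
#'     climbs to its equilibrium within the horizon), the DD
#'     slope solved so the average carrying capacity is 45,000 at the
#'     realized covariate means; detection p = 0.8; counts missing in
#'     years 10 and 20 (two gap years, as in a 1977-2012 survey missing
#'     1986 and 1996).}
#'   \item{`growth_to_K`}{plain Ricker truth (no covariates): intrinsic
#'     rate 0.2, K = 50,000, p = 0.9, start at 5,000.}
#'   \item{`exponential`}{no density dependence in truth: constant
#'     per-capita growth 0.05 from 5,000, p = 0.8 (covariate series are
#'     still simulated so any candidate model can be fitted).}
#'   \item{`covariate_driven`}{no DD; growth responds to the temperature
#'     anomaly (effect 0.1) around a baseline rate 0.03.}
#' }
#'
#' @param name scenario name.
#' @param T override the series length (default 36).
#' @param seed integer seed controlling every random component.
#' @return A `guanaco_data` object whose `truth` element stores the
#'   generating `spec`, `beta`, `p`, `latent` trajectory and `K` (where
#'   defined).
#' @export
make_scenario <- function(name = c("paper_like", "growth_to_K", "exponential",
                                   "covariate_driven"),
                          T = 36L, seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("paper_like", "growth_to_K",
                                             "exponential", "covariate_driven")) {
    stop("unknown scenario '", name[1], "'; valid names: paper_like, ",
         "growth_to_K, exponential, covariate_driven")
  }
  name <- match.arg(name)
  Tn <- as.integer(T)
  years <- seq(1977L, by = 1L, length.out = Tn)

  temp <- simulate_weather(Tn, persistence = 0.3, mean = 3.5, sd = 1.2, seed = seed)
  precip <- simulate_weather(Tn, persistence = 0.2, mean = 370, sd = 60, seed = seed + 1L)
  sheep <- simulate_sheep(Tn, n_knots = 8, seed = seed + 2L)

  data0 <- new_dataset(years, rep(NA_integer_, Tn), temp, precip,
                       years[sheep$year], sheep$count)
  covs <- prepare_covariates(data0)

  setup <- switch(name,
    paper_like = {
      sp <- model_spec(dd = TRUE, covariates = c("Temp", "Sheep"))
      X <- build_design(sp, covs, Tn)
      # DD slope solved so K equals the target at realized covariate means
      xbar <- c(Temp = mean(covs$Temp), Sheep = mean(covs$Sheep))
      num <- 0.18 + 0.05 * xbar[["Temp"]] - 0.05 * xbar[["Sheep"]]
      b1 <- -num / 45000
      list(spec = sp, X = X,
           beta = c(0.18, b1, 0.05, -0.05), p = 0.8, n0 = 3000,
           missing = c(10L, 20L))
    },
    growth_to_K = {
      sp <- model_spec(dd = TRUE)
      list(spec = sp, X = build_design(sp, covs, Tn),
           beta = c(0.2, -4e-6), p = 0.9, n0 = 5000, missing = integer())
    },
    exponential = {
      sp <- model_spec()
      list(spec = sp, X = build_design(sp, covs, Tn),
           beta = 0.05, p = 0.8, n0 = 5000, missing = integer())
    },
    covariate_driven = {
      sp <- model_spec(covariates = "Temp")
      list(spec = sp, X = build_design(sp, covs, Tn),
           beta = c(0.03, 0.1), p = 0.8, n0 = 5000, missing = integer())
    }
  )

  sim <- simulate_trajectory(
    list(beta = setup$beta, p = setup$p, n0 = setup$n0, T = Tn,
         missing_years = setup$missing, seed = seed + 3L),
    setup$X, setup$spec
  )
  K <- NULL
  if (setup$spec$has_dd) {
    xbar <- vapply(setup$spec$covariates, function(cv) mean(covs[[cv]]), numeric(1))
    K <- carrying_capacity(setup$beta, setup$spec, xbar)
  }
  new_dataset(
    years, sim$counts, temp, precip, years[sheep$year], sheep$count,
    truth = list(spec = setup$spec, beta = setup$beta, p = setup$p,
                 latent = sim$latent, K = K, scenario = name, seed = seed)
  )
}
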