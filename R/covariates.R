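# Covariate preparation: weather anomalies, sheep interpolation/rescaling,
# and the per-model design matrix consumed by the growth function.

#' Weather anomaly transform
#'
#' Centres a complete weather series on its empirical mean, by default also
#' dividing by the sample standard deviation so that effect sizes are
#' comparable across covariates (one unit = one standard deviation).
#'
#' @param v numeric vector, one value per year; must be complete and finite.
#' @param method `"standardized"` (default): `(v - mean(v)) / sd(v)`;
#'   `"centered"`: `v - mean(v)`.
#' @return Numeric vector of anomalies with attributes `center`, `scale`
#'   (1 for `"centered"`) and `kind = "anomaly"`. The output has empirical
#'   mean zero.
#' @examples
#' compute_anomaly(c(1, 2, 3)) # -1, 0, 1
#' @export
compute_anomaly <- function(v, method = c("standardized", "centered")) {
  method <- match.arg(method)
  v <- as.numeric(v)
  if (length(v) < 2L) stop("anomaly transform needs at least 2 values")
  if (any(!is.finite(v))) stop("weather series must be complete: missing or non-finite values found")
  mu <- mean(v)
  s <- sd(v)
  if (s == 0) stop("anomaly transform undefined for a constant series (zero spread)")
  sc <- if (method == "standardized") s else 1
  structure((v - mu) / sc, center = mu, scale = sc, kind = "anomaly")
}

#' Rescale a positive series by its maximum
#'
#' Used for the sheep series: `z_t = v_t / max(v)`, giving values in (0, 1]
#' with maximum exactly 1.
#'
#' @param v numeric vector of strictly positive values.
#' @return Numeric vector in (0, 1] with attributes `scale` (the maximum)
#'   and `kind = "max_rescaled"`.
#' @examples
#' rescale_to_max(c(10, 20, 40)) # 0.25, 0.5, 1
#' @export
rescale_to_max <- function(v) {
  v <- as.numeric(v)
  if (!length(v)) stop("empty series")
  if (any(!is.finite(v)) || any(v <= 0)) stop("all values must be positive and finite")
  m <- max(v)
  structure(v / m, scale = m, kind = "max_rescaled")
}

#' Linear interpolation of a sparse yearly series
#'
#' Fills a yearly grid by straight lines between consecutive observed knots
#' (exact pass-through at knot years). Target years outside the knot span
#' are held flat at the boundary knot value, which avoids extrapolating a
#' trend from the two outermost points.
#'
#' @param years integer vector of knot years (at least 2, strictly increasing).
#' @param values numeric vector of knot values, same length as `years`.
#' @param target_years integer vector of years to fill (typically a full
#'   consecutive range).
#' @return Numeric vector of interpolated values, one per `target_years`.
#' @examples
#' interpolate_linear(c(2000, 2004), c(100, 200), 2000:2004)
#' @export
interpolate_linear <- function(years, values, target_years) {
  if (length(years) < 2L) stop("need at least 2 knots to interpolate")
  stopifnot(length(years) == length(values))
  if (any(!is.finite(years)) || any(!is.finite(values))) stop("knots must be finite")
  if (is.unsorted(years, strictly = TRUE)) stop("knot years must be strictly increasing")
  approx(x = years, y = values, xout = target_years, method = "linear", rule = 2)$y
}

#' Build the design matrix for a growth model
#'
#' Assembles the T-by-k matrix of growth-function regressors for a model
#' specification. Columns are ordered intercept, DD (if present), main
#' covariates, interactions. The DD column holds 1 and interaction columns
#' hold the covariate value only; multiplication by the previous abundance
#' happens inside [growth_expectation()]. Rows are lag-aligned: row `t`
#' holds the covariate values that enter the growth step into year `t`,
#' i.e. the values of year `t - lag` (clamped to the first year).
#'
#' @param spec an [model_spec()] object.
#' @param covariates named list of complete numeric covariate series (length
#'   `T` each, on the transformed scale), with names covering every
#'   covariate the spec uses.
#' @param T series length in years.
#' @param lag integer covariate lag (default 1: growth from year `t-1` to
#'   `t` responds to conditions in year `t-1`).
#' @return A `T x k` numeric matrix with column names and attributes
#'   `mult_by_n` (logical per column: multiplied by previous abundance in
#'   the growth function), `lag` and `label`.
#' @export
build_design <- function(spec, covariates = list(), T, lag = 1L) {
  stopifnot(inherits(spec, "ssm_spec"), T >= 1, lag >= 0)
  cols <- spec_columns(spec)
  needed <- union(spec$covariates, spec$interactions)
  missing_cov <- setdiff(needed, names(covariates))
  if (length(missing_cov)) {
    stop("model '", spec$label, "' needs covariate(s) not supplied: ",
         paste(missing_cov, collapse = ", "))
  }
  idx <- pmax(seq_len(T) - lag, 1L) # lag alignment, flat at the series start
  X <- matrix(1, nrow = T, ncol = spec$k, dimnames = list(NULL, cols$names))
  for (cv in spec$covariates) {
    v <- as.numeric(covariates[[cv]])
    if (length(v) != T || any(!is.finite(v))) stop("covariate '", cv, "' must be complete of length T")
    X[, cv] <- v[idx]
  }
  for (cv in spec$interactions) {
    v <- as.numeric(covariates[[cv]])
    if (length(v) != T || any(!is.finite(v))) stop("covariate '", cv, "' must be complete of length T")
    X[, paste0(cv, ":DD")] <- v[idx]
  }
  structure(X, mult_by_n = cols$mult_by_n, lag = as.integer(lag), label = spec$label)
}
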