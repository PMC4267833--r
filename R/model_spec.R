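# Model specifications: which terms enter the population growth function.
#
# A growth model is exp(b0 + b1*n + sum_j b_j*x_j + sum_j g_j*x_j*n), where
# n is the previous abundance (the density-dependence, DD, regressor), x_j
# are environmental covariates, and the g_j terms are covariate-by-density
# interactions (the covariate modulates the strength of density dependence).

.COVARIATE_NAMES <- c("Temp", "Precip", "Sheep")
.INTERACTION_NAMES <- c("Temp", "Precip")
.TIMES <- "\u00d7" # multiplication sign used in model labels, e.g. "Temp x DD"

#' Define a population growth model
#'
#' Constructs a model specification naming the terms that enter the
#' exponential growth rate: an intercept (always present; the intrinsic
#' growth rate), an optional density-dependence (DD) slope, main-effect
#' covariates from `Temp`, `Precip`, `Sheep`, and covariate-by-density
#' interactions (`Temp`, `Precip`), which scale the DD slope by the
#' covariate value. Interaction terms are permitted without a DD main
#' effect.
#'
#' @param dd logical; include the density-dependence (Ricker) term?
#' @param covariates character vector, subset of `c("Temp","Precip","Sheep")`.
#' @param interactions character vector, subset of `c("Temp","Precip")`;
#'   each contributes a `x_j * n` term to the growth exponent.
#' @return An object of class `ssm_spec` with elements `has_dd`,
#'   `covariates`, `interactions`, `label` and `k` (number of growth
#'   parameters, `1 + has_dd + |covariates| + |interactions|`).
#' @examples
#' model_spec(dd = TRUE, covariates = c("Temp", "Sheep"))
#' @export
model_spec <- function(dd = FALSE, covariates = character(), interactions = character()) {
  stopifnot(is.logical(dd), length(dd) == 1L)
  covariates <- as.character(covariates)
  interactions <- as.character(interactions)
  bad <- setdiff(covariates, .COVARIATE_NAMES)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(interactions, .INTERACTION_NAMES)
  if (length(bad)) stop("unknown interaction covariate(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(covariates) || anyDuplicated(interactions)) {
    stop("duplicated terms in model specification")
  }
  # canonical term order: DD, mains (Temp, Precip, Sheep), interactions
  covariates <- .COVARIATE_NAMES[.COVARIATE_NAMES %in% covariates]
  interactions <- .INTERACTION_NAMES[.INTERACTION_NAMES %in% interactions]
  terms <- c(
    if (dd) "DD",
    covariates,
    if (length(interactions)) paste(interactions, .TIMES, "DD")
  )
  label <- if (length(terms)) paste(terms, collapse = " + ") else "Null"
  structure(
    list(
      has_dd = dd, covariates = covariates, interactions = interactions,
      label = label,
      k = 1L + as.integer(dd) + length(covariates) + length(interactions)
    ),
    class = "ssm_spec"
  )
}

#' Parse a model label into a specification
#'
#' Inverse of the labelling used by [model_spec()]: terms separated by
#' `" + "`, where `"DD"` is the density-dependence slope, a bare covariate
#' name is a main effect and `"<cov> × DD"` is an interaction. `"Null"`
#' denotes the intercept-only exponential model.
#'
#' @param label character scalar, e.g. `"DD + Temp + Sheep"`.
#' @return An `ssm_spec`.
#' @export
spec_from_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label == "Null") return(model_spec())
  terms <- strsplit(label, " + ", fixed = TRUE)[[1]]
  dd <- FALSE
  covs <- character()
  inters <- character()
  inter_pat <- paste0(" ", .TIMES, " DD$")
  for (tm in terms) {
    if (tm == "DD") {
      dd <- TRUE
    } else if (tm %in% .COVARIATE_NAMES) {
      covs <- c(covs, tm)
    } else if (grepl(inter_pat, tm)) {
      inters <- c(inters, sub(inter_pat, "", tm))
    } else {
      stop("cannot parse model term: '", tm, "'")
    }
  }
  sp <- model_spec(dd = dd, covariates = covs, interactions = inters)
  if (sp$label != label) {
    stop("label '", label, "' is not in canonical term order (expected '", sp$label, "')")
  }
  sp
}

#' @export
print.ssm_spec <- function(x, ...) {
  cat("Growth model:", x$label, " (k =", x$k, "parameters)\n")
  invisible(x)
}

# Column bookkeeping shared by the design matrix, the growth function and
# the sampler: names, and which columns are multiplied by previous abundance.
spec_columns <- function(spec) {
  nm <- c(
    "(Intercept)",
    if (spec$has_dd) "DD",
    spec$covariates,
    if (length(spec$interactions)) paste0(spec$interactions, ":DD")
  )
  mult <- c(
    FALSE,
    if (spec$has_dd) TRUE,
    rep(FALSE, length(spec$covariates)),
    rep(TRUE, length(spec$interactions))
  )
  list(names = nm, mult_by_n = mult)
}
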