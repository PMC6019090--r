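#' @keywords internal
.COVARIATES <- c("debark", "prun", "wd", "lma")
.INTERACTIONS <- c("debark:wd", "debark:lma", "prun:wd", "prun:lma")
.TRAITS <- c("wd", "lma")

#' Trait standardization
#'
#' A pair (mean, sd) used to z-score a functional trait so that model
#' coefficients refer to "an average tree" and raw-scale back-transforms are
#' exact.
#'
#' @param mean Trait mean, in the trait's raw units.
#' @param sd Trait standard deviation, same units; must be > 0.
#' @return An object of class `trait_standardization`.
#' @examples
#' std <- trait_standardization(0.56, 0.1121)
#' @export
trait_standardization <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd <= 0) stop("trait_standardization: 'sd' must be > 0", call. = FALSE)
  structure(list(mean = mean, sd = sd), class = "trait_standardization")
}

#' Default wood-density standardization
#'
#' Mean 0.56 g cm^-3 with SD reconstructed as 0.005 * sqrt(503) ~ 0.1121
#' g cm^-3 (the published per-tree spread recovered from a standard error at
#' n = 503). This is the scale on which the wood-density coefficients and the
#' zero-cost threshold are expressed.
#'
#' @return A `trait_standardization`.
#' @export
default_wd_standardization <- function() {
  trait_standardization(0.56, 0.005 * sqrt(503))
}

#' Default leaf-mass-per-area standardization
#'
#' Mean 58.17 g m^-2, SD 7.62 g m^-2.
#'
#' @return A `trait_standardization`.
#' @export
default_lma_standardization <- function() {
  trait_standardization(58.17, 7.62)
}

#' Specify the covariate structure on Gmax
#'
#' A growth-model specification names which covariates (debarking and pruning
#' fractions; z-scored wood density and leaf mass per area) and which
#' trait-by-disturbance interactions enter the linear predictor of the
#' size-dependent growth maximum Gmax. Strong heredity is enforced: an
#' interaction may only appear together with both of its main effects.
#'
#' @param covariates Character vector, subset of
#'   `c("debark", "prun", "wd", "lma")`, in the order coefficients are
#'   reported.
#' @param interactions Character vector, subset of
#'   `c("debark:wd", "debark:lma", "prun:wd", "prun:lma")`.
#' @param standardization Named list with optional entries `wd` and `lma`,
#'   each a [trait_standardization()]. A trait used by the spec with no entry
#'   here is standardized from the data at fit time.
#' @return An object of class `growth_model_spec`.
#' @seealso [model0_spec()], [model1_spec()], [model2_spec()], [model3_spec()]
#' @export
growth_model_spec <- function(covariates = character(),
                              interactions = character(),
                              standardization = list()) {
  covariates <- as.character(covariates)
  interactions <- as.character(interactions)
  bad <- setdiff(covariates, .COVARIATES)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(interactions, .INTERACTIONS)
  if (length(bad))
    stop("unknown interaction(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(covariates) || anyDuplicated(interactions))
    stop("duplicated terms in model spec", call. = FALSE)
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    miss <- setdiff(parts, covariates)
    if (length(miss))
      stop("strong heredity violated: interaction '", ia,
           "' lacks main effect(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  if (!is.list(standardization))
    stop("'standardization' must be a list", call. = FALSE)
  for (nm in names(standardization)) {
    if (!nm %in% .TRAITS)
      stop("standardization supplied for unknown trait '", nm, "'",
           call. = FALSE)
    if (!inherits(standardization[[nm]], "trait_standardization"))
      stop("standardization$", nm, " must be a trait_standardization",
           call. = FALSE)
  }
  structure(list(covariates = covariates, interactions = interactions,
                 standardization = standardization),
            class = "growth_model_spec")
}

#' @rdname growth_model_spec
#' @param x A `growth_model_spec`.
#' @export
spec_terms <- function(x) {
  stopifnot(inherits(x, "growth_model_spec"))
  c(x$covariates, x$interactions)
}

#' Canonical model specifications
#'
#' The four covariate structures of the analysis: `model0_spec()` has no
#' covariates (pure size-dependent growth); `model1_spec()` adds the
#' debarking and pruning fractions; `model2_spec()` adds z-scored wood
#' density and leaf mass per area; `model3_spec()` is the structure retained
#' by forward selection: pruning, wood density and their interaction.
#'
#' @param wd_std,lma_std Trait standardizations used to z-score the traits;
#'   defaults are the published species-level values.
#' @return A [growth_model_spec()].
#' @export
model0_spec <- function() growth_model_spec()

#' @rdname model0_spec
#' @export
model1_spec <- function() growth_model_spec(c("debark", "prun"))

#' @rdname model0_spec
#' @export
model2_spec <- function(wd_std = default_wd_standardization(),
                        lma_std = default_lma_standardization()) {
  growth_model_spec(c("wd", "lma"),
                    standardization = list(wd = wd_std, lma = lma_std))
}

#' @rdname model0_spec
#' @export
model3_spec <- function(wd_std = default_wd_standardization()) {
  growth_model_spec(c("prun", "wd"), "prun:wd",
                    standardization = list(wd = wd_std))
}

#' Growth-model parameter vector
#'
#' Bundles the parameters of the hump-shaped growth model: the baseline
#' maximum `gmax_base` of log(AGR+1) (the Gmax of an undisturbed average
#' tree), the diameter `dopt` at which growth peaks, the residual SD `sigma`
#' on the log(AGR+1) scale, and one coefficient per covariate/interaction
#' term of the accompanying spec.
#'
#' @param gmax_base Baseline Gmax, log(AGR+1) units.
#' @param dopt Diameter at maximum growth, cm; must be > 0.
#' @param sigma Residual SD, log(AGR+1) units; must be > 0.
#' @param theta Named numeric vector of term coefficients (names are spec
#'   terms such as `"prun"` or `"prun:wd"`); may be empty.
#' @return An object of class `growth_params`.
#' @examples
#' # the size-only model at its published point estimates
#' growth_params(0.36, 8.76, 0.51)
#' @export
growth_params <- function(gmax_base, dopt, sigma, theta = numeric()) {
  stopifnot(is.numeric(gmax_base), length(gmax_base) == 1L,
            is.numeric(dopt), length(dopt) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(theta))
  if (!is.finite(dopt) || dopt <= 0) stop("'dopt' must be > 0", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be > 0", call. = FALSE)
  if (length(theta) && is.null(names(theta)))
    stop("'theta' must be named by model term", call. = FALSE)
  structure(list(gmax_base = gmax_base, dopt = dopt, sigma = sigma,
                 theta = theta),
            class = "growth_params")
}

.check_params_spec <- function(params, spec) {
  terms <- spec_terms(spec)
  if (length(params$theta) != length(terms) ||
      (length(terms) && !all(terms %in% names(params$theta))))
    stop("theta names do not match spec terms (",
         paste(terms, collapse = ", "), ")", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.growth_model_spec <- function(x, ...) {
  cov <- if (length(x$covariates)) paste(x$covariates, collapse = ", ")
         else "(none)"
  ia <- if (length(x$interactions)) paste(x$interactions, collapse = ", ")
        else "(none)"
  cat("Growth model spec\n  covariates:   ", cov,
      "\n  interactions: ", ia, "\n", sep = "")
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth parameters: gmax_base =", format(x$gmax_base),
      " dopt =", format(x$dopt), "cm  sigma =", format(x$sigma), "\n")
  if (length(x$theta)) {
    cat("  theta:\n")
    print(x$theta)
  }
  invisible(x)
}
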