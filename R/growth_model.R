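#' Linear predictor for the growth maximum Gmax
#'
#' Computes the per-tree growth maximum
#' `Gmax_i = gmax_base + sum_k theta_k x_k + sum_jk theta_jk x_j x_k` for the
#' covariate structure in `spec`. Disturbance covariates (`debark`, `prun`)
#' are fractions in \[0, 1\]; traits (`wd`, `lma`) must already be z-scored
#' (see [standardize_trait()]), so `gmax_base` refers to an undisturbed tree
#' of average trait values.
#'
#' @param params A [growth_params()] whose `theta` matches `spec`.
#' @param spec A [growth_model_spec()].
#' @param covariates Named list or data frame supplying a value (scalar or
#'   vector) for every covariate in `spec`; interaction columns are formed
#'   internally as products.
#' @return Numeric vector of Gmax values.
#' @examples
#' p <- growth_params(0.44, 8.76, 0.51, c(debark = 0.12, prun = -0.24))
#' gmax_linear(p, model1_spec(), list(debark = 0, prun = 1))  # 0.20
#' @export
gmax_linear <- function(params, spec, covariates = list()) {
  stopifnot(inherits(params, "growth_params"),
            inherits(spec, "growth_model_spec"))
  .check_params_spec(params, spec)
  g <- params$gmax_base
  if (!length(spec$covariates)) return(g)
  covariates <- as.list(covariates)
  for (cv in spec$covariates) {
    x <- covariates[[cv]]
    if (is.null(x))
      stop("missing covariate value for term '", cv, "'", call. = FALSE)
    if (cv %in% c("debark", "prun")) .check_fraction(x, cv)
    g <- g + params$theta[[cv]] * x
  }
  for (ia in spec$interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    g <- g + params$theta[[ia]] * covariates[[parts[1L]]] * covariates[[parts[2L]]]
  }
  unname(g)
}

.check_fraction <- function(x, name) {
  if (any(is.na(x)))
    stop("'", name, "' contains missing values", call. = FALSE)
  if (any(x > 1 & x <= 100))
    stop("'", name, "' has values in (1, 100]; intensities are fractions ",
         "in [0, 1] - divide percentages by 100", call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("'", name, "' must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Hump-shaped mean of log(AGR+1)
#'
#' The modelled mean annual growth on the log(AGR+1) scale:
#' `Gmax_i * exp(-0.5 * log(dbh / dopt)^2)`, a Gaussian in log-diameter that
#' peaks exactly at `dbh = dopt` and is symmetric in `log(dbh / dopt)`.
#'
#' @inheritParams gmax_linear
#' @param dbh Diameter at breast height, cm; must be > 0.
#' @param spec Optional [growth_model_spec()]; `NULL` means no covariates.
#' @param warn_negative Warn when a covariate combination drives `Gmax_i`
#'   negative (the mean then dips below zero, which is permitted but usually
#'   signals extreme extrapolation).
#' @return Mean of log(AGR+1), same length as `dbh` (or the covariates).
#' @examples
#' p <- growth_params(0.36, 8.76, 0.51)
#' mean_log_agr(8.76, p)            # 0.36, the peak
#' mean_log_agr(8.76 * exp(1), p)   # 0.36 * exp(-1/2)
#' @export
mean_log_agr <- function(dbh, params, spec = NULL, covariates = list(),
                         warn_negative = TRUE) {
  stopifnot(is.numeric(dbh), inherits(params, "growth_params"))
  if (any(!is.finite(dbh)) || any(dbh <= 0))
    stop("'dbh' must be > 0", call. = FALSE)
  g <- if (is.null(spec)) params$gmax_base
       else gmax_linear(params, spec, covariates)
  if (warn_negative && any(g < 0))
    warning("Gmax_i is negative for some covariate values; ",
            "the modelled mean growth dips below zero", call. = FALSE)
  g * exp(-0.5 * log(dbh / params$dopt)^2)
}

#' Design columns for a model spec
#'
#' Builds the per-tree covariate matrix required by `spec` from a record
#' table: disturbance fractions are used as-is and traits are z-scored with
#' the spec's standardization (estimated from the data when the spec carries
#' none). Interaction columns are products of their constituents.
#'
#' @param records Tree-record data frame (see [read_tree_table()]).
#' @param spec A [growth_model_spec()].
#' @return List with `X` (matrix, one column per spec term; 0-column for the
#'   covariate-free model) and `standardization` (named list of
#'   [trait_standardization()] actually used).
#' @export
build_design <- function(records, spec) {
  stopifnot(is.data.frame(records), inherits(spec, "growth_model_spec"))
  n <- nrow(records)
  std_used <- list()
  cols <- list()
  for (cv in spec$covariates) {
    if (cv %in% .TRAITS) {
      sdz <- standardize_trait(records[[cv]], spec$standardization[[cv]])
      cols[[cv]] <- sdz$z
      std_used[[cv]] <- sdz$std
    } else {
      .check_fraction(records[[cv]], cv)
      cols[[cv]] <- records[[cv]]
    }
  }
  for (ia in spec$interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    cols[[ia]] <- cols[[parts[1L]]] * cols[[parts[2L]]]
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(numeric(), n, 0L)
  colnames(X) <- names(cols)
  list(X = X, standardization = std_used)
}

#' Gaussian log-likelihood of the growth model
#'
#' Sum over trees of the normal log-density of log(AGR+1) at the hump-shaped
#' mean, with SD `sigma`. DBH at the first census drives the size term.
#'
#' @param records Tree-record data frame with columns `dbh_t0`, `agr`, and
#'   any covariates `spec` needs.
#' @param params A [growth_params()].
#' @param spec A [growth_model_spec()] (default: no covariates).
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(records, params, spec = model0_spec()) {
  stopifnot(is.data.frame(records), inherits(params, "growth_params"))
  bad <- which(records$agr <= -1)
  if (length(bad))
    stop("agr <= -1 (log(agr+1) undefined) for tree_id: ",
         paste(records$tree_id[bad], collapse = ", "), call. = FALSE)
  des <- build_design(records, spec)
  eta <- params$gmax_base +
    if (ncol(des$X)) drop(des$X %*% params$theta[colnames(des$X)]) else 0
  mu <- eta * exp(-0.5 * log(records$dbh_t0 / params$dopt)^2)
  sum(stats::dnorm(log(records$agr + 1), mu, params$sigma, log = TRUE))
}

#' Simulate annual growth from the model
#'
#' Draws log(AGR+1) from its normal model and back-transforms, so every
#' simulated AGR exceeds -1 by construction.
#'
#' @inheritParams mean_log_agr
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of AGR draws, cm yr^-1.
#' @export
simulate_agr <- function(dbh, params, spec = NULL, covariates = list(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- mean_log_agr(dbh, params, spec, covariates, warn_negative = FALSE)
  n <- max(length(dbh), length(mu))
  y <- stats::rnorm(n, mu, params$sigma)
  exp(y) - 1
}
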