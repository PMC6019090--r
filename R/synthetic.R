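#' Configuration of the synthetic inventory generator
#'
#' Describes a synthetic tree inventory with the structure of the field
#' study: populations nested in ecological zones, a lower DBH census limit of
#' 2 cm, size-dependent pruning and debarking intensities, per-tree wood
#' density and leaf mass per area, and one-year growth generated from a
#' hump-shaped growth model.
#'
#' @param n_trees Total number of trees (default 503).
#' @param n_populations Number of populations (default 12), spread as evenly
#'   as possible across zones and holding near-equal numbers of trees.
#' @param n_zones Number of ecological zones (default 2).
#' @param dbh_meanlog,dbh_sdlog Log-normal DBH law (cm); the default median
#'   of 10 cm with log-SD 0.8 gives a size structure peaking near the
#'   diameter of maximum growth. Truncated below at `dbh_min`.
#' @param dbh_min Census threshold, cm (default 2).
#' @param wd_mean,wd_sd Wood-density law, g cm^-3 (defaults 0.56 and
#'   0.005*sqrt(503) ~ 0.1121).
#' @param lma_mean,lma_sd Leaf-mass-per-area law, g m^-2 (defaults 58.17,
#'   7.62).
#' @param reserve_wd_effect How much lower (g cm^-3) mean WD is for trees
#'   inside forest reserves (default 0.06); used only by
#'   [generate_reserve_trait_set()].
#' @param prun_size_slope,debark_size_slope Slope of the logistic link
#'   between standardized log-DBH and expected disturbance intensity; 0 makes
#'   intensity independent of size.
#' @param disturbance_precision Beta precision of intensity noise around its
#'   logistic mean (larger = less noisy).
#' @param growth_truth List with `params` ([growth_params()]) and `spec`
#'   ([growth_model_spec()]) used to simulate growth; default is the
#'   covariate-free model at its published point estimates (Gmax 0.36,
#'   Dopt 8.76 cm, sigma 0.51).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_trees = 503L, n_populations = 12L,
                             n_zones = 2L,
                             dbh_meanlog = log(10), dbh_sdlog = 0.8,
                             dbh_min = 2,
                             wd_mean = 0.56, wd_sd = 0.005 * sqrt(503),
                             lma_mean = 58.17, lma_sd = 7.62,
                             reserve_wd_effect = 0.06,
                             prun_size_slope = 1.5, debark_size_slope = 1.5,
                             disturbance_precision = 2,
                             growth_truth = list(
                               params = growth_params(0.36, 8.76, 0.51),
                               spec = model0_spec()),
                             seed = 1L) {
  cfg <- list(n_trees = as.integer(n_trees),
              n_populations = as.integer(n_populations),
              n_zones = as.integer(n_zones),
              dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
              dbh_min = dbh_min,
              wd_mean = wd_mean, wd_sd = wd_sd,
              lma_mean = lma_mean, lma_sd = lma_sd,
              reserve_wd_effect = reserve_wd_effect,
              prun_size_slope = prun_size_slope,
              debark_size_slope = debark_size_slope,
              disturbance_precision = disturbance_precision,
              growth_truth = growth_truth,
              seed = as.integer(seed))
  .validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

.validate_generator_config <- function(cfg) {
  fail <- function(field, msg)
    stop("invalid generator config: '", field, "' ", msg, call. = FALSE)
  if (cfg$n_zones < 1L) fail("n_zones", "must be >= 1")
  if (cfg$n_populations < cfg$n_zones)
    fail("n_populations", "must be >= n_zones")
  if (cfg$n_trees < cfg$n_populations) fail("n_trees", "must be >= n_populations")
  for (f in c("dbh_sdlog", "wd_sd", "lma_sd", "disturbance_precision"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) fail(f, "must be > 0")
  if (!is.finite(cfg$dbh_min) || cfg$dbh_min <= 0) fail("dbh_min", "must be > 0")
  if (cfg$reserve_wd_effect < 0) fail("reserve_wd_effect", "must be >= 0")
  gt <- cfg$growth_truth
  if (!is.list(gt) || !inherits(gt$params, "growth_params") ||
      !inherits(gt$spec, "growth_model_spec"))
    fail("growth_truth", "must be a list(params = growth_params, spec = growth_model_spec)")
  .check_params_spec(gt$params, gt$spec)
  produced <- .COVARIATES
  miss <- setdiff(gt$spec$covariates, produced)
  if (length(miss))
    fail("growth_truth", paste0("spec uses covariate(s) the generator does ",
                                "not produce: ", paste(miss, collapse = ", ")))
  if (!is.finite(cfg$seed)) fail("seed", "must be a finite integer")
  invisible(TRUE)
}

# truncated-below normal / lognormal draws via the inverse CDF, so that a
# single runif stream carries all randomness deterministically
.rtnorm_low <- function(n, mean, sd, low) {
  stats::qnorm(stats::runif(n, stats::pnorm(low, mean, sd), 1), mean, sd)
}

.rdisturb <- function(dbh, cfg, slope) {
  z <- (log(dbh) - cfg$dbh_meanlog) / cfg$dbh_sdlog
  mu <- stats::plogis(slope * z)
  phi <- cfg$disturbance_precision
  stats::rbeta(length(dbh), mu * phi, (1 - mu) * phi)
}

.generate_records <- function(config, with_reserves) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_trees
  # populations spread evenly over zones, trees spread evenly over populations
  pop <- sort(rep_len(seq_len(cfg$n_populations), n))
  zone_of_pop <- rep_len(seq_len(cfg$n_zones), cfg$n_populations)
  if (with_reserves) {
    # within each zone, alternate populations in and out of reserves
    reserve_of_pop <- logical(cfg$n_populations)
    for (z in seq_len(cfg$n_zones)) {
      idx <- which(zone_of_pop == z)
      reserve_of_pop[idx] <- seq_along(idx) %% 2L == 1L
    }
  } else {
    reserve_of_pop <- rep(FALSE, cfg$n_populations)
  }
  in_reserve <- reserve_of_pop[pop]

  dbh0 <- exp(.rtnorm_low(n, cfg$dbh_meanlog, cfg$dbh_sdlog,
                          log(cfg$dbh_min)))
  prun <- .rdisturb(dbh0, cfg, cfg$prun_size_slope)
  debark <- .rdisturb(dbh0, cfg, cfg$debark_size_slope)
  wd_mean_i <- cfg$wd_mean - ifelse(in_reserve, cfg$reserve_wd_effect, 0)
  wd <- .rtnorm_low(n, wd_mean_i, cfg$wd_sd, 0.01)
  lma <- .rtnorm_low(n, cfg$lma_mean, cfg$lma_sd, 0.01)

  rec <- data.frame(
    tree_id = sprintf("T%04d", seq_len(n)),
    population_id = sprintf("P%02d", pop),
    zone = sprintf("zone%d", zone_of_pop[pop]),
    in_reserve = in_reserve,
    dbh_t0 = dbh0, dbh_t1 = NA_real_, agr = NA_real_,
    debark = debark, prun = prun, wd = wd, lma = lma,
    stringsAsFactors = FALSE)

  truth <- cfg$growth_truth
  des <- build_design(rec, truth$spec)
  covs <- as.data.frame(des$X)
  agr <- simulate_agr(dbh0, truth$params, truth$spec, covs)
  rec$dbh_t1 <- rec$dbh_t0 + agr
  rec$agr <- rec$dbh_t1 - rec$dbh_t0
  attr(rec, "truth") <- list(params = truth$params, spec = truth$spec,
                             standardization = des$standardization,
                             seed = cfg$seed)
  rec
}

#' Generate a synthetic tree inventory
#'
#' Draws a full inventory under `config`: DBH from a truncated log-normal,
#' size-dependent pruning and debarking fractions, wood density and LMA from
#' normal laws, and one-year growth simulated from the configured
#' truth model. All trees are outside reserves (`in_reserve = FALSE`); use
#' [generate_reserve_trait_set()] for the reserve contrast. The generating
#' parameters are attached as a `"truth"` attribute (a side channel, never an
#' analysis column); persist them with [write_truth_json()].
#'
#' @param config A [generator_config()].
#' @return Data frame of tree records (one row per tree) with columns
#'   `tree_id`, `population_id`, `zone`, `in_reserve`, `dbh_t0`, `dbh_t1`,
#'   `agr`, `debark`, `prun`, `wd`, `lma`.
#' @export
generate_tree_records <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .validate_generator_config(config)
  .generate_records(config, with_reserves = FALSE)
}

#' Generate an inventory with a reserve contrast in wood density
#'
#' As [generate_tree_records()], but roughly half the populations in each
#' zone are flagged as inside a forest reserve, and inside-reserve trees draw
#' wood density from a mean lowered by `reserve_wd_effect` — emulating lower
#' WD where pruning pressure has historically been low.
#'
#' @inheritParams generate_tree_records
#' @return Data frame of tree records; `in_reserve` is `TRUE` for trees of
#'   reserve populations.
#' @export
generate_reserve_trait_set <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .validate_generator_config(config)
  .generate_records(config, with_reserves = TRUE)
}

#' Persist the latent generating truth of a synthetic inventory
#'
#' @param records A data frame from [generate_tree_records()] or
#'   [generate_reserve_trait_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(records, path) {
  truth <- attr(records, "truth")
  if (is.null(truth))
    stop("records carry no 'truth' attribute", call. = FALSE)
  out <- list(
    params = list(gmax_base = truth$params$gmax_base,
                  dopt = truth$params$dopt,
                  sigma = truth$params$sigma,
                  theta = as.list(truth$params$theta)),
    spec = list(covariates = truth$spec$covariates,
                interactions = truth$spec$interactions),
    standardization = lapply(truth$standardization,
                             function(s) list(mean = s$mean, sd = s$sd)),
    seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
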