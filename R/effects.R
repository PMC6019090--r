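#' Point parameters of a fitted model
#'
#' Packs a fit's maximum-likelihood draw (plus any fixed values) into a
#' [growth_params()] usable by the prediction and effect functions.
#'
#' @param fit A `growth_fit`.
#' @return A [growth_params()].
#' @export
point_params <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  terms <- spec_terms(fit$spec)
  growth_params(fit$point[["gmax_base"]], fit$point[["dopt"]],
                fit$point[["sigma"]],
                if (length(terms)) fit$point[terms] else numeric())
}

#' Predicted annual growth at a point parameter vector
#'
#' Back-transformed model mean, `exp(mean_log_agr) - 1`, in cm yr^-1.
#'
#' @inheritParams mean_log_agr
#' @export
predict_agr <- function(dbh, params, spec = NULL, covariates = list()) {
  exp(mean_log_agr(dbh, params, spec, covariates, warn_negative = FALSE)) - 1
}

#' Pruning-cost surface over diameter and wood density
#'
#' The growth cost of pruning — predicted annual growth of a not-pruned tree
#' minus that of a fully pruned one (pruning fraction 0 vs 1), back-
#' transformed to cm yr^-1 — evaluated on a DBH-by-WD lattice. Wood density
#' is supplied on the raw g cm^-3 scale and z-scored internally with `std`.
#'
#' @param params A [growth_params()] containing at least the `prun` and
#'   `prun:wd` coefficients (e.g. [point_params()] of a fit of
#'   [model3_spec()]).
#' @param std The wood-density [trait_standardization()].
#' @param dbh_grid Increasing DBH grid, cm.
#' @param wd_grid Increasing WD grid, g cm^-3.
#' @param spec The model spec the parameters belong to (default
#'   [model3_spec()]).
#' @return An object of class `pruning_cost_grid`: `dbh`, `wd`, and `cost`
#'   (matrix, rows = DBH, columns = WD).
#' @export
pruning_cost <- function(params, std, dbh_grid, wd_grid,
                         spec = model3_spec(std)) {
  stopifnot(inherits(params, "growth_params"),
            inherits(std, "trait_standardization"))
  need <- c("prun", "prun:wd")
  miss <- setdiff(need, names(params$theta))
  if (length(miss))
    stop("params lack required coefficient(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.unsorted(dbh_grid, strictly = TRUE) ||
      is.unsorted(wd_grid, strictly = TRUE))
    stop("grids must be strictly increasing", call. = FALSE)
  z <- (wd_grid - std$mean) / std$sd
  cost <- matrix(NA_real_, length(dbh_grid), length(wd_grid))
  base_cov <- list(debark = 0, lma = 0)
  for (j in seq_along(z)) {
    cov0 <- c(base_cov, list(wd = z[j], prun = 0))
    cov1 <- c(base_cov, list(wd = z[j], prun = 1))
    cost[, j] <- predict_agr(dbh_grid, params, spec, cov0) -
      predict_agr(dbh_grid, params, spec, cov1)
  }
  structure(list(dbh = dbh_grid, wd = wd_grid, cost = cost),
            class = "pruning_cost_grid")
}

#' Wood density at which the pruning cost vanishes
#'
#' Solves `theta_P + theta_P:WD * z = 0` for the z-scored wood density and
#' maps the root back to the raw scale: `std$mean + std$sd * (-theta_P /
#' theta_P:WD)`. Above this density a tree incurs no pruning-related growth
#' reduction at any diameter.
#'
#' @inheritParams pruning_cost
#' @return Raw-scale WD threshold, g cm^-3. When `theta_P` and `theta_P:WD`
#'   are both zero the cost vanishes for every tree: the trait mean is
#'   returned with attribute `degenerate = TRUE`.
#' @examples
#' p <- growth_params(0.41, 8.76, 0.51,
#'                    c(prun = -0.18, wd = -0.10, "prun:wd" = 0.12))
#' zero_cost_wd(p, default_wd_standardization())  # ~0.73 g cm^-3
#' @export
zero_cost_wd <- function(params, std) {
  stopifnot(inherits(params, "growth_params"),
            inherits(std, "trait_standardization"))
  th_p <- params$theta[["prun"]]
  th_pwd <- if ("prun:wd" %in% names(params$theta))
    params$theta[["prun:wd"]] else 0
  if (th_pwd == 0) {
    if (th_p == 0)
      return(structure(std$mean, degenerate = TRUE))
    stop("no pruning-by-WD interaction: the pruning cost never vanishes",
         call. = FALSE)
  }
  std$mean + std$sd * (-th_p / th_pwd)
}

#' Compare wood density inside versus outside forest reserves
#'
#' Two-sample t-test of per-tree wood density between outside-reserve and
#' inside-reserve trees; pooled-variance (Student's) by default, Welch's
#' behind `welch = TRUE`. The reported difference is signed outside minus
#' inside.
#'
#' @param records Tree-record data frame with `in_reserve` and `wd`.
#' @param welch Use Welch's unequal-variance test instead of Student's.
#' @return List of class `reserve_wd_test`: `difference` (g cm^-3),
#'   `statistic`, `df`, `p_value`, `method`, and group means/sizes.
#' @export
reserve_wd_test <- function(records, welch = FALSE) {
  stopifnot(is.data.frame(records))
  outside <- records$wd[!records$in_reserve]
  inside <- records$wd[records$in_reserve]
  if (length(outside) < 2L || length(inside) < 2L)
    stop("both reserve groups need >= 2 trees", call. = FALSE)
  if (stats::var(outside) == 0 && stats::var(inside) == 0 &&
      mean(outside) == mean(inside)) {
    # identical degenerate groups: no evidence of a difference
    return(structure(list(difference = 0, statistic = 0,
                          df = length(outside) + length(inside) - 2,
                          p_value = 1, method = "student",
                          mean_outside = mean(outside),
                          mean_inside = mean(inside),
                          n_outside = length(outside),
                          n_inside = length(inside)),
                     class = "reserve_wd_test"))
  }
  tt <- stats::t.test(outside, inside, var.equal = !welch)
  structure(list(difference = mean(outside) - mean(inside),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (welch) "welch" else "student",
                 mean_outside = mean(outside), mean_inside = mean(inside),
                 n_outside = length(outside), n_inside = length(inside)),
            class = "reserve_wd_test")
}

#' @export
print.reserve_wd_test <- function(x, ...) {
  cat("WD outside - inside reserves: ", format(x$difference, digits = 4),
      " g cm^-3 (", x$method, " t = ", format(x$statistic, digits = 4),
      ", df = ", format(x$df, digits = 5), ", p = ",
      format.pval(x$p_value, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Binned growth summary across diameter classes
#'
#' Bins trees by DBH on the log scale and computes per-bin boxplot
#' statistics: quartiles, Tukey whiskers (most extreme observations within
#' 1.5 IQR of the box) and outliers beyond them.
#'
#' @param records Tree-record data frame.
#' @param n_bins Number of DBH bins (default 10).
#' @return Object of class `binned_growth_summary`: `table` (one row per
#'   non-empty bin with edges in cm, `n`, `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`) and `outliers` (list of AGR values per
#'   bin).
#' @export
binned_agr_summary <- function(records, n_bins = 10L) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) stop("no records to summarize", call. = FALSE)
  ld <- log(records$dbh_t0)
  br <- seq(min(ld), max(ld), length.out = n_bins + 1L)
  br[1L] <- br[1L] - 1e-9
  bin <- cut(ld, br, labels = FALSE)
  rows <- list()
  outliers <- list()
  for (b in sort(unique(bin))) {
    x <- records$agr[bin == b]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    lo_lim <- q[1L] - 1.5 * iqr
    hi_lim <- q[3L] + 1.5 * iqr
    inside <- x[x >= lo_lim & x <= hi_lim]
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, lower_cm = exp(max(br[b], min(ld))), upper_cm = exp(br[b + 1L]),
      n = length(x), q1 = q[1L], median = q[2L], q3 = q[3L],
      whisker_low = min(inside), whisker_high = max(inside))
    outliers[[as.character(b)]] <- x[x < lo_lim | x > hi_lim]
  }
  structure(list(table = do.call(rbind, rows), outliers = outliers,
                 n_total = nrow(records)),
            class = "binned_growth_summary")
}

#' @export
print.binned_growth_summary <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  n_out <- sum(lengths(x$outliers))
  cat(n_out, "outlier(s) beyond 1.5 IQR whiskers;", x$n_total,
      "trees in total\n")
  invisible(x)
}

#' @export
plot.binned_growth_summary <- function(x, ...) {
  k <- nrow(x$table)
  stats_m <- t(as.matrix(x$table[, c("whisker_low", "q1", "median", "q3",
                                     "whisker_high")]))
  z <- list(stats = stats_m, n = x$table$n, conf = stats_m[c(2, 4), ,
                                                           drop = FALSE],
            out = unlist(x$outliers),
            group = rep(seq_len(k), lengths(x$outliers)),
            names = sprintf("%.1f", sqrt(x$table$lower_cm * x$table$upper_cm)))
  graphics::bxp(z, xlab = "DBH bin midpoint (cm)",
                ylab = "AGR (cm / yr)", ...)
  invisible(x)
}

#' @export
plot.pruning_cost_grid <- function(x, ...) {
  graphics::image(x$dbh, x$wd, x$cost, xlab = "DBH (cm)",
                  ylab = "Wood density (g cm^-3)", ...)
  graphics::contour(x$dbh, x$wd, x$cost, add = TRUE)
  invisible(x)
}

#' Posterior predicted growth trajectory
#'
#' Median and central 95% envelope of the back-transformed growth curve
#' `exp(mean_log_agr) - 1` over (thinned) posterior draws, for a fixed
#' covariate profile.
#'
#' @param fit A `growth_fit`.
#' @param dbh_grid DBH grid, cm.
#' @param covariates Named list of covariate values on the model scale
#'   (fractions for `debark`/`prun`, z-scores for traits); defaults to zero
#'   for every spec covariate (an undisturbed average tree).
#' @param n_draws Number of thinned draws (default 500).
#' @return Data frame with `dbh`, `median`, `lower`, `upper` (cm yr^-1), of
#'   class `predicted_trajectory`.
#' @export
predicted_trajectory <- function(fit, dbh_grid, covariates = list(),
                                 n_draws = 500L) {
  stopifnot(inherits(fit, "growth_fit"))
  spec <- fit$spec
  for (cv in spec$covariates)
    if (is.null(covariates[[cv]])) covariates[[cv]] <- 0
  S_all <- nrow(fit$draws)
  idx <- unique(round(seq(1L, S_all, length.out = min(n_draws, S_all))))
  curves <- matrix(NA_real_, length(idx), length(dbh_grid))
  terms <- spec_terms(spec)
  dm <- as.matrix(fit$draws[, fit$free, drop = FALSE])
  for (s in seq_along(idx)) {
    d <- dm[idx[s], ]
    pp <- growth_params(d[["gmax_base"]],
                        if (is.null(fit$fixed$dopt)) d[["dopt"]]
                        else fit$fixed$dopt,
                        if (is.null(fit$fixed$sigma)) d[["sigma"]]
                        else fit$fixed$sigma,
                        if (length(terms)) d[terms] else numeric())
    curves[s, ] <- predict_agr(dbh_grid, pp, spec, covariates)
  }
  qs <- apply(curves, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  structure(data.frame(dbh = dbh_grid, median = qs[1L, ], lower = qs[2L, ],
                       upper = qs[3L, ]),
            class = c("predicted_trajectory", "data.frame"))
}
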