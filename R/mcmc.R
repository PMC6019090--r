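#' MCMC sampler configuration
#'
#' @param chains Number of chains (>= 2; default 4).
#' @param iterations Iterations per chain (default 20000).
#' @param burn_fraction Fraction of each chain discarded as burn-in
#'   (default 0.5); proposal scales adapt only during burn-in. At least 1000
#'   post-burn-in draws per chain are required.
#' @param adapt_window Iterations between proposal-scale adjustments during
#'   burn-in (default 50).
#' @param seed Integer seed; identical config and data give identical draws.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iterations = 20000L,
                        burn_fraction = 0.5, adapt_window = 50L, seed = 1L) {
  chains <- as.integer(chains)
  iterations <- as.integer(iterations)
  if (chains < 2L) stop("'chains' must be >= 2", call. = FALSE)
  if (burn_fraction < 0 || burn_fraction >= 1)
    stop("'burn_fraction' must be in [0, 1)", call. = FALSE)
  kept <- iterations - floor(iterations * burn_fraction)
  if (kept < 1000L)
    stop("need >= 1000 post-burn-in draws per chain; got ", kept,
         call. = FALSE)
  structure(list(chains = chains, iterations = iterations,
                 burn_fraction = burn_fraction,
                 adapt_window = as.integer(adapt_window),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Prior descriptors
#'
#' Constructors for the prior families understood by the sampler. The
#' default set ([default_priors()]) is weakly informative: Normal(0, 10^2)
#' on `gmax_base` and every coefficient, log-uniform on \[2, 200\] cm for
#' `dopt`, and half-Cauchy(1) for `sigma`.
#'
#' @param mean,sd,min,max,scale Family parameters.
#' @return A prior descriptor list.
#' @export
prior_normal <- function(mean = 0, sd = 10) {
  stopifnot(sd > 0)
  list(dist = "normal", mean = mean, sd = sd)
}

#' @rdname prior_normal
#' @export
prior_flat <- function() list(dist = "flat")

#' @rdname prior_normal
#' @export
prior_loguniform <- function(min = 2, max = 200) {
  stopifnot(min > 0, max > min)
  list(dist = "loguniform", min = min, max = max)
}

#' @rdname prior_normal
#' @export
prior_halfcauchy <- function(scale = 1) {
  stopifnot(scale > 0)
  list(dist = "halfcauchy", scale = scale)
}

#' @rdname prior_normal
#' @details `default_priors()` returns a named list with entries
#'   `gmax_base`, `theta` (applied to every coefficient without its own
#'   entry), `dopt` and `sigma`; any entry may be overridden, and a prior
#'   for a single coefficient may be supplied under its term name (e.g.
#'   `"prun:wd"`).
#' @export
default_priors <- function() {
  list(gmax_base = prior_normal(0, 10), theta = prior_normal(0, 10),
       dopt = prior_loguniform(2, 200), sigma = prior_halfcauchy(1))
}

.prior_for <- function(name, priors, is_theta) {
  p <- priors[[name]]
  if (is.null(p) && is_theta) p <- priors$theta
  if (is.null(p))
    stop("no prior supplied for parameter '", name, "'", call. = FALSE)
  p
}

# log prior density on the sampling scale (natural value 'nat'; 'logscale'
# marks parameters sampled as log(nat), which adds the Jacobian log(nat))
.log_prior <- function(prior, nat, logscale) {
  lp <- switch(prior$dist,
    normal = stats::dnorm(nat, prior$mean, prior$sd, log = TRUE),
    flat = 0,
    loguniform = if (nat < prior$min || nat > prior$max) -Inf else -log(nat),
    halfcauchy = if (nat <= 0) -Inf else
      log(2) - log(pi * prior$scale * (1 + (nat / prior$scale)^2)),
    stop("unknown prior dist '", prior$dist, "'", call. = FALSE))
  if (logscale && is.finite(lp)) lp <- lp + log(nat)
  lp
}

# crude moment-based initialization: binned means of log(AGR+1) on the
# log-DBH axis locate the hump
.init_point <- function(ld, y, n_bins = 8L) {
  br <- seq(min(ld), max(ld), length.out = n_bins + 1L)
  br[1L] <- br[1L] - 1e-8
  bin <- cut(ld, br, labels = FALSE)
  bm <- tapply(y, bin, mean)
  centers <- (br[-1L] + br[-length(br)]) / 2
  k <- which.max(bm)
  list(gmax = max(bm[k], 0.05),
       dopt = exp(centers[as.integer(names(bm)[k])]),
       sigma = max(stats::sd(y), 0.05))
}

#' Fit a growth model by adaptive Metropolis-within-Gibbs MCMC
#'
#' Samples the posterior of the hump-shaped growth model: `gmax_base`, one
#' coefficient per spec term, `dopt` and `sigma` (the latter two on the log
#' scale for positivity, and optionally held fixed). Proposal scales adapt
#' toward a 20--50% acceptance rate during burn-in only. Convergence is
#' summarized by split-R-hat and an autocorrelation-based effective sample
#' size; values beyond the thresholds (R-hat > 1.05, ESS < 400) raise
#' entries in the result's `warnings` field without hiding the draws.
#'
#' @param records Tree-record data frame (>= 10 rows; see
#'   [read_tree_table()]).
#' @param spec A [growth_model_spec()].
#' @param priors Prior list as from [default_priors()].
#' @param mcmc An [mcmc_config()].
#' @param fixed Named list of parameters to hold fixed (only `dopt` and/or
#'   `sigma`), e.g. `list(dopt = 8.76, sigma = 0.51)`.
#' @return An object of class `growth_fit` with elements `draws` (data frame
#'   with `chain`, `iteration`, one column per free parameter, `loglik`),
#'   `point` (parameter vector of the retained draw with maximum
#'   log-likelihood), `rhat`, `ess`, `acceptance`, `warnings`, plus the
#'   `spec`, trait `standardization`, `priors`, `mcmc` and `fixed` used.
#' @export
fit_growth_model <- function(records, spec = model0_spec(),
                             priors = default_priors(),
                             mcmc = mcmc_config(), fixed = list()) {
  stopifnot(is.data.frame(records), inherits(spec, "growth_model_spec"),
            inherits(mcmc, "mcmc_config"))
  if (nrow(records) < 10L)
    stop("need at least 10 records to fit", call. = FALSE)
  bad <- which(records$agr <= -1)
  if (length(bad))
    stop("agr <= -1 for tree_id: ",
         paste(records$tree_id[bad], collapse = ", "), call. = FALSE)
  if (length(setdiff(names(fixed), c("dopt", "sigma"))))
    stop("only 'dopt' and 'sigma' can be fixed", call. = FALSE)

  des <- build_design(records, spec)
  X <- des$X
  terms <- colnames(X)
  if (length(terms)) {
    v0 <- apply(X, 2L, stats::sd)
    if (any(v0 == 0))
      stop("zero variance in data for model term(s): ",
           paste(terms[v0 == 0], collapse = ", "), call. = FALSE)
  }
  y <- log(records$agr + 1)
  ld <- log(records$dbh_t0)
  n <- length(y)

  free <- c("gmax_base", terms,
            if (is.null(fixed$dopt)) "dopt",
            if (is.null(fixed$sigma)) "sigma")
  logscale <- free %in% c("dopt", "sigma")
  names(logscale) <- free
  prior_list <- lapply(free, function(nm)
    .prior_for(nm, priors, is_theta = nm %in% terms))
  names(prior_list) <- free

  set.seed(mcmc$seed)
  init <- .init_point(ld, y)
  dopt_prior <- prior_list[["dopt"]]
  if (!is.null(dopt_prior) && dopt_prior$dist == "loguniform")
    init$dopt <- min(max(init$dopt, dopt_prior$min * 1.05),
                     dopt_prior$max * 0.95)

  burn <- floor(mcmc$iterations * mcmc$burn_fraction)
  kept <- mcmc$iterations - burn
  p <- length(free)
  chain_draws <- vector("list", mcmc$chains)
  chain_ll <- vector("list", mcmc$chains)
  acc_post <- matrix(0, mcmc$chains, p, dimnames = list(NULL, free))

  l2pi <- log(2 * pi)
  for (ch in seq_len(mcmc$chains)) {
    # overdispersed start per chain
    v <- c(gmax_base = init$gmax + stats::rnorm(1, 0, 0.05),
           stats::setNames(stats::rnorm(length(terms), 0, 0.02), terms),
           if (is.null(fixed$dopt))
             c(dopt = log(init$dopt) + stats::runif(1, -0.2, 0.2)),
           if (is.null(fixed$sigma))
             c(sigma = log(init$sigma) + stats::runif(1, -0.1, 0.1)))
    v <- v[free]
    if (is.null(fixed$dopt) && !is.null(dopt_prior) &&
        dopt_prior$dist == "loguniform")
      v[["dopt"]] <- min(max(v[["dopt"]], log(dopt_prior$min) + 0.01),
                         log(dopt_prior$max) - 0.01)
    nat <- ifelse(logscale, exp(v), v)
    dopt <- if (is.null(fixed$dopt)) nat[["dopt"]] else fixed$dopt
    sigma <- if (is.null(fixed$sigma)) nat[["sigma"]] else fixed$sigma
    th <- if (length(terms)) nat[terms] else numeric()
    g <- nat[["gmax_base"]]

    eta <- g + if (length(terms)) drop(X %*% th) else 0
    w <- exp(-0.5 * (ld - log(dopt))^2)
    mu <- eta * w
    rss <- sum((y - mu)^2)
    ll <- -0.5 * n * l2pi - n * log(sigma) - 0.5 * rss / sigma^2
    lpv <- vapply(free, function(nm)
      .log_prior(prior_list[[nm]], nat[[nm]], logscale[[nm]]), numeric(1))
    if (!is.finite(ll) || !all(is.finite(lpv)))
      stop("non-finite likelihood or prior at initialization (chain ", ch,
           "): check records and priors", call. = FALSE)

    scales <- stats::setNames(rep(0.1, p), free)
    scales["gmax_base"] <- 0.05
    if (length(terms)) scales[terms] <- 0.05
    acc_win <- stats::setNames(numeric(p), free)
    draws <- matrix(NA_real_, kept, p, dimnames = list(NULL, free))
    llkeep <- numeric(kept)

    for (it in seq_len(mcmc$iterations)) {
      for (j in seq_len(p)) {
        nm <- free[j]
        vj_new <- v[[j]] + stats::rnorm(1, 0, scales[[j]])
        nat_new <- if (logscale[[j]]) exp(vj_new) else vj_new
        lp_new <- .log_prior(prior_list[[j]], nat_new, logscale[[j]])
        if (is.finite(lp_new)) {
          if (nm == "sigma") {
            rss_new <- rss
            eta_new <- eta; w_new <- w; mu_new <- mu
            ll_new <- -0.5 * n * l2pi - n * vj_new -
              0.5 * rss / nat_new^2
          } else {
            if (nm == "gmax_base") {
              eta_new <- eta + (nat_new - g)
              w_new <- w
            } else if (nm == "dopt") {
              eta_new <- eta
              w_new <- exp(-0.5 * (ld - vj_new)^2)
            } else {
              eta_new <- eta + (nat_new - th[[nm]]) * X[, nm]
              w_new <- w
            }
            mu_new <- eta_new * w_new
            rss_new <- sum((y - mu_new)^2)
            ll_new <- -0.5 * n * l2pi - n * log(sigma) -
              0.5 * rss_new / sigma^2
          }
          if (log(stats::runif(1)) < (ll_new + lp_new) - (ll + lpv[[j]])) {
            v[[j]] <- vj_new
            lpv[[j]] <- lp_new
            ll <- ll_new
            eta <- eta_new; w <- w_new; mu <- mu_new; rss <- rss_new
            if (nm == "gmax_base") g <- nat_new
            else if (nm == "dopt") dopt <- nat_new
            else if (nm == "sigma") sigma <- nat_new
            else th[[nm]] <- nat_new
            acc_win[[j]] <- acc_win[[j]] + 1
            if (it > burn) acc_post[ch, j] <- acc_post[ch, j] + 1
          }
        }
      }
      if (it <= burn && it %% mcmc$adapt_window == 0L) {
        rate <- acc_win / mcmc$adapt_window
        scales[rate < 0.2] <- scales[rate < 0.2] * 0.7
        scales[rate > 0.5] <- scales[rate > 0.5] * 1.4
        acc_win[] <- 0
      }
      if (it > burn) {
        k <- it - burn
        draws[k, ] <- ifelse(logscale, exp(v), v)
        llkeep[k] <- ll
      }
    }
    chain_draws[[ch]] <- draws
    chain_ll[[ch]] <- llkeep
  }
  acc_post <- acc_post / kept

  rhat <- vapply(free, function(nm)
    split_rhat(lapply(chain_draws, function(d) d[, nm])), numeric(1))
  ess <- vapply(free, function(nm)
    ess_autocorr(lapply(chain_draws, function(d) d[, nm])), numeric(1))

  all_draws <- do.call(rbind, chain_draws)
  ll_all <- unlist(chain_ll)
  best <- which.max(ll_all)
  point <- all_draws[best, ]
  if (!is.null(fixed$dopt)) point <- c(point, dopt = fixed$dopt)
  if (!is.null(fixed$sigma)) point <- c(point, sigma = fixed$sigma)

  warnings <- character()
  if (any(rhat > 1.05))
    warnings <- c(warnings, paste0("split-Rhat > 1.05 for: ",
      paste(free[rhat > 1.05], collapse = ", ")))
  if (any(ess < 400))
    warnings <- c(warnings, paste0("ESS < 400 for: ",
      paste(free[ess < 400], collapse = ", ")))

  df <- data.frame(chain = rep(seq_len(mcmc$chains), each = kept),
                   iteration = rep(seq_len(kept), mcmc$chains))
  df <- cbind(df, as.data.frame(all_draws))
  df$loglik <- ll_all

  structure(list(draws = df, free = free, point = point,
                 point_loglik = ll_all[best],
                 rhat = rhat, ess = ess,
                 acceptance = colMeans(acc_post),
                 warnings = warnings,
                 spec = spec, standardization = des$standardization,
                 priors = priors, mcmc = mcmc, fixed = fixed, n = n),
            class = "growth_fit")
}

#' Split-R-hat convergence diagnostic
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' statistic is computed over the resulting 2M half-chains.
#'
#' @param chains List of numeric vectors (one per chain, equal lengths).
#' @return The split-R-hat statistic (1 at perfect mixing).
#' @export
split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    m <- floor(length(x) / 2)
    halves <- c(halves, list(x[seq_len(m)]), list(x[m + seq_len(m)]))
  }
  nn <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Autocorrelation-based effective sample size
#'
#' Chain-averaged autocorrelations, truncated at the first negative
#' paired sum (Geyer's initial positive sequence), give the integrated
#' autocorrelation time; ESS = (total draws) / tau.
#'
#' @inheritParams split_rhat
#' @return Estimated effective sample size across all chains.
#' @export
ess_autocorr <- function(chains) {
  nn <- length(chains[[1L]])
  total <- nn * length(chains)
  max_lag <- min(200L, nn - 2L)
  acs <- vapply(chains, function(x) {
    if (stats::sd(x) == 0) return(rep(0, max_lag + 1L))
    stats::acf(x, lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[, 1L, 1L]
  }, numeric(max_lag + 1L))
  rho <- rowMeans(acs)
  tau <- 1
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  min(total, total / tau)
}

#' Summarize a fitted growth model
#'
#' One row per free parameter: the point estimate (the retained draw with
#' maximum likelihood), the posterior mean, the central 95% credibility
#' interval (2.5 and 97.5 percentiles), split-R-hat and effective sample
#' size.
#'
#' @param fit A `growth_fit` from [fit_growth_model()].
#' @return Data frame with columns `parameter`, `point`, `mean`, `lower`,
#'   `upper`, `rhat`, `ess`.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  out <- lapply(fit$free, function(nm) {
    x <- fit$draws[[nm]]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = nm, point = unname(fit$point[nm]),
               mean = mean(x), lower = q[1L], upper = q[2L],
               rhat = unname(fit$rhat[nm]), ess = unname(fit$ess[nm]))
  })
  do.call(rbind, out)
}

#' @export
summary.growth_fit <- function(object, ...) posterior_summary(object)

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth model fit:", length(x$free), "free parameter(s),",
      max(x$draws$chain), "chains x", max(x$draws$iteration),
      "retained draws\n")
  print(posterior_summary(x), row.names = FALSE, digits = 4)
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Does a parameter's 95% credibility interval exclude zero?
#'
#' @param fit A `growth_fit`.
#' @param parameter Parameter name (e.g. `"prun"` or `"prun:wd"`).
#' @return `TRUE` iff 0 lies outside the central 95% interval.
#' @export
credible_interval_excludes_zero <- function(fit, parameter) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!parameter %in% fit$free)
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  q <- stats::quantile(fit$draws[[parameter]], c(0.025, 0.975), names = FALSE)
  q[1L] > 0 || q[2L] < 0
}

#' Widely applicable information criterion of a fit
#'
#' WAIC on the deviance scale, `-2 * (lppd - p_waic)`, from the pointwise
#' log-likelihood matrix of thinned posterior draws. Lower is better.
#'
#' @param fit A `growth_fit`.
#' @param records The records the model was fitted to.
#' @param n_draws Number of (evenly thinned) draws used (default 500).
#' @return A list with `waic`, `lppd` and `p_waic`.
#' @export
waic <- function(fit, records, n_draws = 500L) {
  stopifnot(inherits(fit, "growth_fit"), is.data.frame(records))
  spec <- fit$spec
  spec$standardization <- utils::modifyList(spec$standardization,
                                            fit$standardization)
  des <- build_design(records, spec)
  X <- des$X
  y <- log(records$agr + 1)
  ld <- log(records$dbh_t0)
  S_all <- nrow(fit$draws)
  idx <- unique(round(seq(1L, S_all, length.out = min(n_draws, S_all))))
  ll <- matrix(NA_real_, length(idx), length(y))
  for (s in seq_along(idx)) {
    d <- fit$draws[idx[s], ]
    dopt <- if (is.null(fit$fixed$dopt)) d[["dopt"]] else fit$fixed$dopt
    sigma <- if (is.null(fit$fixed$sigma)) d[["sigma"]] else fit$fixed$sigma
    eta <- d[["gmax_base"]] +
      if (ncol(X)) drop(X %*% unlist(d[colnames(X)])) else 0
    mu <- eta * exp(-0.5 * (ld - log(dopt))^2)
    ll[s, ] <- stats::dnorm(y, mu, sigma, log = TRUE)
  }
  mx <- apply(ll, 2L, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2L, mx)))))
  p_waic <- sum(apply(ll, 2L, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Export posterior draws and summaries
#'
#' @param fit A `growth_fit`.
#' @param draws_path Optional CSV path for the draws (one column per
#'   parameter plus `chain` and `iteration`).
#' @param summary_path Optional JSON path for the summary table.
#' @return The summary data frame, invisibly.
#' @export
export_fit <- function(fit, draws_path = NULL, summary_path = NULL) {
  s <- posterior_summary(fit)
  if (!is.null(draws_path))
    utils::write.csv(fit$draws, draws_path, row.names = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(list(summary = s, warnings = fit$warnings,
                              fixed = fit$fixed),
                         summary_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(s)
}
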