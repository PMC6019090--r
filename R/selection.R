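#' Forward selection of trait-by-disturbance interactions
#'
#' Starting from the covariate-free model, each remaining candidate
#' interaction is fitted in turn (together with both of its main effects,
#' enforcing strong heredity) and scored; the best-scoring candidate is
#' adopted if it improves on the current model, otherwise selection stops.
#' Main effects are kept once adopted even if their own intervals include
#' zero. The default score is WAIC with an improvement threshold of 2
#' deviance units; `criterion = "ci"` instead adopts the candidate whose
#' interaction coefficient's 95% interval excludes zero (largest |mean|/SD
#' first).
#'
#' @param records Tree-record data frame.
#' @param candidates Character vector of candidate interactions, a subset of
#'   `c("debark:wd", "debark:lma", "prun:wd", "prun:lma")`; order breaks
#'   ties.
#' @param priors,mcmc Passed to [fit_growth_model()]; each candidate fit
#'   derives its seed deterministically from `mcmc$seed`.
#' @param criterion `"waic"` (default) or `"ci"`.
#' @param threshold Minimum WAIC drop counted as an improvement (default 2).
#' @param standardization Trait standardizations given to candidate specs
#'   (default: the published trait means/SDs).
#' @return An object of class `selection_result`: `final_spec`, `final_fit`,
#'   `steps` (per-step candidate scores and decisions) and
#'   `stopping_reason`.
#' @export
forward_select_interactions <- function(records,
                                        candidates = .INTERACTIONS,
                                        priors = default_priors(),
                                        mcmc = mcmc_config(),
                                        criterion = c("waic", "ci"),
                                        threshold = 2,
                                        standardization = list(
                                          wd = default_wd_standardization(),
                                          lma = default_lma_standardization())) {
  criterion <- match.arg(criterion)
  bad <- setdiff(candidates, .INTERACTIONS)
  if (length(bad))
    stop("unknown candidate(s): ", paste(bad, collapse = ", "), call. = FALSE)

  spec_for <- function(covs, ints) {
    std <- standardization[intersect(.TRAITS, covs)]
    growth_model_spec(covs, ints, standardization = std)
  }
  current_spec <- spec_for(character(), character())
  current_fit <- fit_growth_model(records, current_spec, priors, mcmc)
  current_score <- waic(current_fit, records)$waic
  remaining <- candidates
  steps <- list()
  stopping <- NULL
  step_i <- 0L

  while (length(remaining)) {
    step_i <- step_i + 1L
    rows <- list()
    fits <- list()
    for (k in seq_along(remaining)) {
      cand <- remaining[k]
      parts <- strsplit(cand, ":", fixed = TRUE)[[1L]]
      covs <- union(current_spec$covariates, parts)
      ints <- c(current_spec$interactions, cand)
      cand_mcmc <- mcmc
      cand_mcmc$seed <- mcmc$seed + 1000L * step_i + k
      fit <- tryCatch(
        fit_growth_model(records, spec_for(covs, ints), priors, cand_mcmc),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("candidate '", cand, "' skipped: ",
                conditionMessage(fit), call. = FALSE)
        rows[[k]] <- data.frame(candidate = cand, waic = NA_real_,
                                excludes_zero = NA, error = conditionMessage(fit),
                                stringsAsFactors = FALSE)
        next
      }
      fits[[cand]] <- fit
      rows[[k]] <- data.frame(
        candidate = cand,
        waic = waic(fit, records)$waic,
        excludes_zero = credible_interval_excludes_zero(fit, cand),
        error = NA_character_, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$current_waic <- current_score

    ok <- which(!is.na(tab$waic))
    if (!length(ok)) {
      stopping <- "all candidate fits failed"
      steps[[step_i]] <- tab
      break
    }
    if (criterion == "waic") {
      best <- ok[which.min(tab$waic[ok])]
      improves <- current_score - tab$waic[best] >= threshold
    } else {
      excl <- ok[which(tab$excludes_zero[ok])]
      if (length(excl)) {
        zstat <- vapply(tab$candidate[excl], function(cn) {
          x <- fits[[cn]]$draws[[cn]]
          abs(mean(x)) / stats::sd(x)
        }, numeric(1))
        best <- excl[which.max(zstat)]
        improves <- TRUE
      } else {
        best <- ok[1L]
        improves <- FALSE
      }
    }
    tab$adopted <- seq_len(nrow(tab)) == best & improves
    steps[[step_i]] <- tab
    if (!improves) {
      stopping <- "no candidate improves the current model"
      break
    }
    cand <- tab$candidate[best]
    parts <- strsplit(cand, ":", fixed = TRUE)[[1L]]
    current_spec <- spec_for(union(current_spec$covariates, parts),
                             c(current_spec$interactions, cand))
    current_fit <- fits[[cand]]
    current_score <- tab$waic[best]
    remaining <- setdiff(remaining, cand)
    if (!length(remaining)) stopping <- "no candidates left"
  }
  if (is.null(stopping)) stopping <- "no candidates supplied"

  structure(list(final_spec = current_spec, final_fit = current_fit,
                 steps = steps, stopping_reason = stopping,
                 criterion = criterion, threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Forward interaction selection (", x$criterion, ")\n", sep = "")
  for (i in seq_along(x$steps)) {
    cat("Step ", i, ":\n", sep = "")
    print(x$steps[[i]], row.names = FALSE, digits = 5)
  }
  cat("Stopping: ", x$stopping_reason, "\nFinal model terms: ",
      if (length(spec_terms(x$final_spec)))
        paste(spec_terms(x$final_spec), collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Write a selection audit trail as JSON
#'
#' @param result A `selection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  out <- list(
    final_spec = list(covariates = result$final_spec$covariates,
                      interactions = result$final_spec$interactions),
    stopping_reason = result$stopping_reason,
    criterion = result$criterion, threshold = result$threshold,
    steps = result$steps)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
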