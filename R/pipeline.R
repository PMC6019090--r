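.spec_for_model <- function(model) {
  switch(as.character(model),
         "0" = model0_spec(), "1" = model1_spec(),
         "2" = model2_spec(), "3" = model3_spec(),
         stop("unknown model '", model, "'; use 0, 1, 2 or 3", call. = FALSE))
}

.pipe_log <- function(dir, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  cat(line, "\n", file = file.path(dir, "pipeline.log"), append = TRUE,
      sep = "")
  invisible(line)
}

.mcmc_from_config <- function(config) {
  mcmc_config(chains = config$chains %||% 4L,
              iterations = config$iterations %||% 20000L,
              burn_fraction = config$burn_fraction %||% 0.5,
              seed = config$seed %||% 1L)
}

#' Run one stage of the analysis pipeline
#'
#' Ties the package's stages into a file-based pipeline. Each stage reads
#' and writes CSV/JSON under `config$output_dir`, embeds the configuration
#' hash and seed in its outputs, and appends to a timestamped
#' `pipeline.log`. Stages:
#' \describe{
#'   \item{`simulate`}{Generate a synthetic inventory (`trees.csv`,
#'     `truth.json`). `config$reserves = TRUE` uses the reserve-contrast
#'     generator; other `generator_config()` fields pass through
#'     `config$generator`.}
#'   \item{`traits`}{Compute per-tree WD and LMA from raw measurement CSVs
#'     (`config$cores`, `config$leaves`) into `traits.csv`.}
#'   \item{`fit`}{Fit `config$model` (0--3) to `config$input`; writes
#'     `draws_model<m>.csv` and `summary_model<m>.json`.}
#'   \item{`select`}{Forward interaction selection on `config$input`;
#'     writes `selection.json`.}
#'   \item{`effects`}{Fit the interaction model and write the pruning-cost
#'     grid (`cost_grid.csv`), the zero-cost WD threshold and reserve t-test
#'     (`effects.json`) and the binned growth summary
#'     (`binned_summary.csv`).}
#'   \item{`report`}{Fit models 0--3 and collate their summaries into
#'     `report.json`.}
#' }
#'
#' @param subcommand One of `"simulate"`, `"traits"`, `"fit"`, `"select"`,
#'   `"effects"`, `"report"`.
#' @param config Named list: `output_dir` (required), `seed`, `input`,
#'   `model`, `chains`, `iterations`, `burn_fraction`, `generator`,
#'   `reserves`, `criterion`, `welch`, `n_bins`, `cores`, `leaves`.
#' @return Named list of the paths written, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "traits", "fit",
                                        "select", "effects", "report"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  known <- c("output_dir", "seed", "input", "model", "chains", "iterations",
             "burn_fraction", "generator", "reserves", "criterion", "welch",
             "n_bins", "cores", "leaves")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dir <- config$output_dir
  if (is.null(dir)) stop("config$output_dir is required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  hash <- config_hash(list(subcommand, config[setdiff(names(config),
                                                      "output_dir")]))
  meta <- c(config_hash = hash, seed = as.character(seed))
  .pipe_log(dir, "start ", subcommand, " config_hash=", hash, " seed=", seed)
  out <- switch(subcommand,
    simulate = {
      gen_args <- config$generator %||% list()
      gen_args$seed <- seed
      cfg <- do.call(generator_config, gen_args)
      rec <- if (isTRUE(config$reserves)) generate_reserve_trait_set(cfg)
             else generate_tree_records(cfg)
      trees <- file.path(dir, "trees.csv")
      write_tree_table(rec, trees, meta = meta)
      truth <- file.path(dir, "truth.json")
      write_truth_json(rec, truth)
      list(trees = trees, truth = truth)
    },
    traits = {
      cores <- utils::read.csv(config$cores, stringsAsFactors = FALSE)
      leaves <- utils::read.csv(config$leaves, stringsAsFactors = FALSE)
      tr <- compute_traits(cores, leaves)
      path <- file.path(dir, "traits.csv")
      con <- file(path, "w"); on.exit(close(con), add = TRUE)
      writeLines(paste0("# ", names(meta), "=", meta), con)
      utils::write.csv(tr, con, row.names = FALSE, quote = FALSE)
      list(traits = path)
    },
    fit = {
      rec <- read_tree_table(config$input)
      model <- config$model %||% 0L
      fit <- fit_growth_model(rec, .spec_for_model(model),
                              mcmc = .mcmc_from_config(config))
      dpath <- file.path(dir, sprintf("draws_model%s.csv", model))
      spath <- file.path(dir, sprintf("summary_model%s.json", model))
      utils::write.csv(fit$draws, dpath, row.names = FALSE)
      jsonlite::write_json(
        list(config_hash = hash, seed = seed, model = model,
             summary = posterior_summary(fit), warnings = fit$warnings),
        spath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      list(draws = dpath, summary = spath)
    },
    select = {
      rec <- read_tree_table(config$input)
      sel <- forward_select_interactions(
        rec, mcmc = .mcmc_from_config(config),
        criterion = config$criterion %||% "waic")
      path <- file.path(dir, "selection.json")
      write_selection_json(sel, path)
      list(selection = path)
    },
    effects = {
      rec <- read_tree_table(config$input)
      fit <- fit_growth_model(rec, model3_spec(),
                              mcmc = .mcmc_from_config(config))
      pp <- point_params(fit)
      std <- fit$spec$standardization$wd
      grid <- pruning_cost(pp, std, dbh_grid = seq(2, 60, by = 1),
                           wd_grid = seq(0.3, 0.9, by = 0.02))
      gpath <- file.path(dir, "cost_grid.csv")
      gm <- as.data.frame(grid$cost)
      names(gm) <- sprintf("wd_%0.2f", grid$wd)
      utils::write.csv(cbind(dbh_cm = grid$dbh, gm), gpath,
                       row.names = FALSE)
      res <- tryCatch(reserve_wd_test(rec, welch = isTRUE(config$welch)),
                      error = function(e) NULL)
      epath <- file.path(dir, "effects.json")
      jsonlite::write_json(
        list(config_hash = hash, seed = seed,
             zero_cost_wd = as.numeric(zero_cost_wd(pp, std)),
             reserve_test = if (is.null(res)) NULL else unclass(res)),
        epath, auto_unbox = TRUE, digits = NA)
      bpath <- file.path(dir, "binned_summary.csv")
      bs <- binned_agr_summary(rec, n_bins = config$n_bins %||% 10L)
      utils::write.csv(bs$table, bpath, row.names = FALSE)
      list(cost_grid = gpath, effects = epath, binned = bpath)
    },
    report = {
      rec <- read_tree_table(config$input)
      tabs <- lapply(0:3, function(m) {
        cfgm <- config; cfgm$seed <- seed + m
        fit <- fit_growth_model(rec, .spec_for_model(m),
                                mcmc = .mcmc_from_config(cfgm))
        list(model = m, summary = posterior_summary(fit),
             warnings = fit$warnings)
      })
      path <- file.path(dir, "report.json")
      jsonlite::write_json(list(config_hash = hash, seed = seed,
                                models = tabs),
                           path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      list(report = path)
    })
  .pipe_log(dir, "done ", subcommand)
  invisible(out)
}
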