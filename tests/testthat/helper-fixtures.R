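# Shared fixtures: small seeded inventories and reduced MCMC settings so the
# default test run stays fast while exercising the full code paths.

tiny_config <- function(n = 60, seed = 1, ...) {
  generator_config(n_trees = n, n_populations = 4, n_zones = 2,
                   seed = seed, ...)
}

tiny_records <- function(n = 60, seed = 1, ...) {
  generate_tree_records(tiny_config(n = n, seed = seed, ...))
}

quick_mcmc <- function(seed = 1, chains = 2, iterations = 2400) {
  mcmc_config(chains = chains, iterations = iterations, seed = seed)
}

# Table-style simulation truths used across recovery tests
truth_model0 <- function() {
  list(params = growth_params(0.36, 8.76, 0.51), spec = model0_spec())
}

truth_model1 <- function(theta_d = 0.12, theta_p = -0.24) {
  list(params = growth_params(0.44, 8.76, 0.51,
                              c(debark = theta_d, prun = theta_p)),
       spec = model1_spec())
}

truth_model3 <- function() {
  list(params = growth_params(0.41, 8.76, 0.51,
                              c(prun = -0.18, wd = -0.10, "prun:wd" = 0.12)),
       spec = model3_spec())
}

# minimal hand-built posterior object for interval logic tests
fake_fit <- function(draws_named_list) {
  df <- as.data.frame(draws_named_list)
  structure(list(draws = df, free = names(df)), class = "growth_fit")
}
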