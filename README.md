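# treedisturb

Bayesian analysis of how chronic anthropogenic disturbance — fodder
pruning and medicinal debarking — affects the diameter growth of trees,
and how intraspecific functional traits (wood density, leaf mass per
area) mediate that effect. Built for ecologists analysing two-census
inventory data of repeatedly harvested tree populations, and for
simulation studies of what such designs can and cannot detect.

## The model

One-year absolute growth rate (AGR, cm yr⁻¹) follows a hump-shaped
ontogenetic trajectory,

    log(AGR_i + 1) ~ Normal( Gmax_i · exp(−½ · log²(DBH_i / Dopt)), σ² )

with all covariate structure on the growth maximum:

    Gmax_i = Gmax + Σ_k θ_k · x_ki + Σ_jk θ_jk · x_ji · x_ki

where the x are debarking and pruning fractions in [0, 1] and z-scored
wood density (WD) and leaf mass per area (LMA). Named specs cover the
standard structures: size-only (`model0_spec()`), disturbance
(`model1_spec()`), traits (`model2_spec()`), and pruning × wood-density
interaction (`model3_spec()`). Inference is adaptive
Metropolis-within-Gibbs MCMC with split-R̂/ESS diagnostics; interaction
terms are chosen by forward selection under strong heredity with a WAIC
score. Derived quantities include the pruning-cost surface over DBH × WD,
the wood density at which the pruning cost vanishes, reserve-vs-outside
trait comparisons, binned growth summaries and posterior growth
trajectories. A seeded synthetic-inventory generator reproduces the
study design (503 trees, 12 populations, 2 zones, size-dependent
disturbance) for end-to-end testing and parameter-recovery experiments.

## Worked example

```r
library(treedisturb)

# a synthetic inventory with the study's design, growth simulated from the
# size-only model at Gmax = 0.36, Dopt = 8.76 cm, sigma = 0.51
trees <- generate_tree_records(generator_config(seed = 42))

fit <- fit_growth_model(trees, model0_spec(),
                        mcmc = mcmc_config(chains = 4, iterations = 6000,
                                           seed = 1))
print(fit)
#> Growth model fit: 3 free parameter(s), 4 chains x 3000 retained draws
#>  parameter   point    mean  lower   upper  rhat  ess
#>  gmax_base  0.3777  0.3796 0.3229  0.4368 1.002 2719
#>       dopt 10.4698 10.5639 7.8033 14.0568 1.000 2296
#>      sigma  0.5191  0.5216 0.4901  0.5556 1.001 2369
```

The point column is the retained draw of maximum likelihood; `lower` and
`upper` are the central 95% credibility interval. Here the generating
values (0.36, 8.76, 0.51) are recovered within their posterior
uncertainty: growth peaks at a DBH near 9–10 cm at about
exp(0.38) − 1 ≈ 0.46 cm yr⁻¹, with residual SD ≈ 0.52 on the log scale.

Derived effects from interaction-model coefficients:

```r
p3 <- growth_params(0.41, 8.76, 0.51,
                    c(prun = -0.18, wd = -0.10, "prun:wd" = 0.12))
zero_cost_wd(p3, default_wd_standardization())
#> [1] 0.7282075
```

Trees denser than ≈ 0.73 g cm⁻³ are predicted to incur no
pruning-related growth reduction at any diameter. And the reserve
contrast in wood density:

```r
rec <- generate_reserve_trait_set(generator_config(seed = 42))
reserve_wd_test(rec)
#> WD outside - inside reserves: 0.06421 g cm^-3 (student t = 6.585,
#>   df = 501, p = 1.15e-10)
```

`run_pipeline()` ties the stages (`simulate`, `traits`, `fit`, `select`,
`effects`, `report`) into a file-based workflow whose outputs embed the
seed and a config hash. See the vignette
(`vignettes/growth-disturbance-model.Rmd`) for the model's assumptions,
priors, selection procedure and the generator's design rationale.

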