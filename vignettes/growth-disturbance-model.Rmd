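---
title: "Modelling size-dependent tree growth under chronic disturbance"
author: "treedisturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling size-dependent tree growth under chronic disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treedisturb)
```

## The model

Annual diameter growth of trees is hump-shaped over ontogeny: small stems
grow slowly, growth peaks at an intermediate diameter, and large trees grow
slowly again. `treedisturb` models the one-year absolute growth rate (AGR,
cm yr^-1^, the difference between two consecutive DBH censuses) of
individual trees as

$$\log(\mathrm{AGR}_i + 1) \sim \mathcal{N}\!\left(
  G_{\max,i}\, e^{-\tfrac12 \log^2(D_i / D_{\mathrm{opt}})},\;
  \sigma^2\right),$$

a Gaussian curve in log-diameter. $D_i$ is the tree's DBH (cm) at the first
census, $D_{\mathrm{opt}}$ the diameter at which growth peaks, and
$G_{\max,i}$ the maximum of $\log(\mathrm{AGR}+1)$ for tree $i$. The
log(AGR+1) response keeps slightly negative increments (shrinkage,
measurement slack) in the support: any AGR $> -1$ is admissible.

All covariate structure enters through $G_{\max,i}$:

$$G_{\max,i} = G_{\max} + \sum_k \theta_k x_{ki}
  + \sum_{jk} \theta_{jk} x_{ji} x_{ki},$$

with four available covariates — the debarking fraction, the pruning
fraction, wood density (WD) and leaf mass per area (LMA) — and
trait-by-disturbance interaction terms under *strong heredity* (an
interaction enters only with both main effects). Four named structures
cover the analysis: the size-only model (`model0_spec()`), disturbance only
(`model1_spec()`: debark + prun), traits only (`model2_spec()`: WD + LMA),
and the interaction structure retained by forward selection
(`model3_spec()`: prun + WD + prun×WD). $D_{\mathrm{opt}}$ and $\sigma$
deliberately carry no covariates: putting the same covariates in several
parts of this nonlinear model is poorly identified, and there is no clear
biological hypothesis for them there. Although the headline fits report
only $G_{\max}$-level coefficients, $D_{\mathrm{opt}}$ and $\sigma$ are
re-estimated in every model rather than pinned at their size-only values.

### Covariate scales

Disturbance intensities are **fractions in [0, 1]** — the proportion of
branches pruned, or of trunk area debarked — so $\theta_P$ is the full
contrast between an unpruned and a completely pruned tree. Values in
(1, 100] are rejected with a hint to divide percentages by 100; silently
rescaling would change every coefficient's meaning.

Traits enter **z-scored**, so $G_{\max}$ refers to "an average tree". A
`trait_standardization` (mean, SD) travels with the model spec, making
raw-scale back-transforms exact. The package defaults are a WD mean of
0.56 g cm^-3^ with SD $0.005\sqrt{503} \approx 0.1121$ g cm^-3^ (a per-tree
spread reconstructed from a standard error at the study's n = 503 — the
only reading under which the interaction coefficients and the zero-cost
threshold below are mutually consistent) and an LMA mean of 58.17 g m^-2^
with SD 7.62 g m^-2^.

One related caveat: wood density is computed as oven-dry mass divided by
*fresh* cylinder volume of an increment core (`wood_density()`,
`core_volume()`), the wood-economics convention; a density of ~0.56
g cm^-3^ is only consistent with this direction of the ratio. Per-tree LMA
is the unweighted mean of the (conventionally three) sampled leaves.

## Inference

The posterior of $(G_{\max}, \theta, D_{\mathrm{opt}}, \sigma)$ is sampled
with an adaptive random-walk **Metropolis-within-Gibbs** sampler
(`fit_growth_model()`). Choices that matter:

* **Parameterization.** $D_{\mathrm{opt}}$ and $\sigma$ are sampled on the
  log scale, which enforces positivity and symmetrizes their posteriors.
* **Priors** (defaults, weakly informative): $G_{\max}$ and every
  $\theta \sim \mathcal{N}(0, 10^2)$; $D_{\mathrm{opt}}$ log-uniform on
  [2, 200] cm (the census threshold to far beyond the species' maximum
  size); $\sigma \sim$ half-Cauchy(1). All are overridable, including a
  flat prior used by the conjugate closed-form check in the test suite.
* **Initialization.** $G_{\max}$ starts at the maximum of binned
  log(AGR+1) means over log-DBH bins and $D_{\mathrm{opt}}$ at that bin's
  center, jittered per chain for overdispersed starts; coefficients start
  near 0. A non-finite likelihood or prior at initialization is a hard
  error, not a silent restart.
* **Adaptation.** Per-parameter proposal scales are tuned every 50
  iterations *during burn-in only* (target acceptance 20--50%); the
  post-burn-in kernel is fixed, so detailed balance holds for every
  retained draw.
* **Defaults.** 4 chains × 20,000 iterations, first half discarded. The
  config refuses settings leaving fewer than 1,000 retained draws per
  chain.
* **Diagnostics.** Split-$\widehat{R}$ and an autocorrelation-based ESS per
  parameter; thresholds ($\widehat{R} \le 1.05$, ESS $\ge 400$) raise
  warnings in the result object rather than discarding it.
* **Point estimate.** Summaries report the retained draw maximizing the
  data log-likelihood ("value at maximum likelihood") alongside posterior
  means and central 95% credibility intervals. The best-likelihood-draw
  convention was chosen over MAP or a separate frequentist fit because it
  needs no extra optimization and is well defined for any prior; with
  20k-draw chains it sits close to the MLE.

```{r fit-example, eval = FALSE}
trees <- generate_tree_records(generator_config(seed = 42))
fit <- fit_growth_model(trees, model0_spec(),
                        mcmc = mcmc_config(seed = 1))
posterior_summary(fit)
```

## Forward selection of interactions

`forward_select_interactions()` starts from the size-only model and, at
each step, fits every remaining candidate interaction together with its two
main effects, scores each fit by **WAIC** (deviance scale, computed from
thinned posterior draws), and adopts the best candidate if WAIC drops by at
least 2; otherwise it stops. Ties break by candidate order; main effects
are never removed once adopted, even when their own intervals include zero.
A `criterion = "ci"` alternative adopts candidates whose interaction
interval excludes zero. The full audit trail (per-step scores, adoption
decisions, failures) is kept and serializable (`write_selection_json()`).

The threshold of 2 is the conventional "worth mentioning" deviance
difference; nothing in the problem pins it more precisely. Users should
know its operating characteristics: when an interaction's posterior SD is
comparable to its magnitude — which is exactly the regime of the
pruning×WD effect at the published effect sizes and n = 503 — single
inventories will sometimes fail to clear the threshold or occasionally
admit a spurious term, so the selected structure is itself a noisy
statistic. The test suite treats selection accordingly: structural
properties (heredity, determinism, audit trail) are asserted exactly, while
exact-structure recovery is checked as a multi-seed frequency.

## Derived quantities

**Pruning-cost surface** (`pruning_cost()`): the difference in predicted
growth between a not-pruned and a fully pruned tree,
$(e^{\mu(prun=0)} - 1) - (e^{\mu(prun=1)} - 1)$, on a DBH × WD lattice,
reported on the back-transformed cm yr^-1^ scale. With a negative
$\theta_P$ and positive $\theta_{P\times WD}$ the cost is largest for
intermediate-diameter, low-density trees and shrinks as wood density
rises.

**Zero-cost wood density** (`zero_cost_wd()`): the pruning terms cancel
where $\theta_P + \theta_{P\times WD}\, z = 0$, i.e. at raw wood density
$\mathrm{mean} + \mathrm{sd} \cdot (-\theta_P / \theta_{P\times WD})$.
With point estimates $\theta_P = -0.18$, $\theta_{P\times WD} = 0.12$ and
the default standardization this is $0.56 + 0.1121 \times 1.5 \approx
0.73$ g cm^-3^ — trees at least this dense are predicted to incur no
pruning-related growth reduction at any size. When the interaction is
exactly zero the threshold does not exist (error), unless $\theta_P$ is
also zero, in which case every density is cost-free and the trait mean is
returned with a degeneracy flag.

**Reserve contrast** (`reserve_wd_test()`): a two-sample t-test of wood
density between trees outside and inside forest reserves, pooled-variance
(Student's) by default because that is the named convention for this
comparison; Welch's version sits behind a flag. The sign convention is
outside minus inside.

**Binned growth summary** (`binned_agr_summary()`): DBH classes on the log
scale with per-bin quartiles, Tukey whiskers (most extreme points within
1.5 IQR) and explicit outlier lists. Tukey whiskers were chosen over
min/max whiskers because outliers are reported separately; min/max
whiskers would make the outlier set empty by construction.

**Posterior trajectories** (`predicted_trajectory()`): median and 95%
envelope of $e^{\mu} - 1$ over thinned posterior draws for a fixed
covariate profile.

## The synthetic inventory generator

No field data ship with the package; `generate_tree_records()` produces
inventories with the statistical structure the analysis assumes, so every
stage is testable end to end and parameter-recovery studies are cheap.
What it emulates, and the choices where the design was open:

* **Design**: 503 trees in 12 populations balanced across 2 ecological
  zones; DBH ≥ 2 cm (the census threshold).
* **Size structure**: DBH is log-normal (median 10 cm, log-SD 0.8)
  truncated at 2 cm. The empirical size distribution is not published;
  this law peaks near the diameter of maximum growth, which is the
  size-structure shape of a regenerating dry-forest population and the
  most informative regime for $D_{\mathrm{opt}}$.
* **Disturbance intensities**: pruning and debarking fractions are Beta
  draws whose mean follows a logistic function of standardized log-DBH
  (slope 1.5 by default; 0 switches size dependence off) with precision 2.
  Only "intensity increases with size" is documented for the field system;
  the precision was fixed so that the resulting coefficient uncertainties
  at n = 503 match the published credibility-interval widths (posterior SD
  of $\theta_P \approx 0.10$), i.e. the synthetic design carries the same
  information content as the real one, not more.
* **Traits**: WD ~ Normal(0.56, 0.1121) g cm^-3^ and LMA ~ Normal(58.17,
  7.62) g m^-2^, truncated just above zero. `generate_reserve_trait_set()`
  flags half the populations per zone as inside reserves and lowers their
  WD mean by 0.06 g cm^-3^, emulating disturbance-filtered trait
  divergence; the plain generator leaves all trees outside reserves so the
  overall trait means stay at their configured values.
* **Growth**: simulated from any `growth_params` + `growth_model_spec`
  truth (default: the size-only model at $G_{\max} = 0.36$,
  $D_{\mathrm{opt}} = 8.76$ cm, $\sigma = 0.51$). Simulating on the
  log(AGR+1) scale guarantees AGR > −1; `dbh_t1` is `dbh_t0 + AGR`
  exactly.
* **Blinding**: the generating truth is attached as a side-channel
  attribute and written by `write_truth_json()` to a separate file, never
  as analysis columns.
* **Seeding**: one integer seed drives a single RNG stream in documented
  draw order (DBH, pruning, debarking, WD, LMA, growth); identical configs
  are bit-identical.

What it does **not** emulate — and what green tests therefore do not show
about real inventories: spatial structure and autocorrelation within
populations, population- or zone-level random effects on growth, DBH
measurement error, more than two censuses, mortality and recruitment, and
any trait-disturbance feedback operating through tree history rather than
the modelled covariates.

## Numerical choices and degenerate inputs

* Natural logarithms throughout.
* The likelihood is evaluated with cached per-term quantities (the
  Gaussian size weight, the linear predictor, the residual sum of squares)
  updated incrementally per parameter move, keeping a 4 × 20k-iteration
  fit on 503 trees in the order of seconds.
* $G_{\max,i}$ may go negative under extreme covariate extrapolation; the
  mean function then dips below zero. This is permitted (and flagged with
  a warning in user-facing prediction paths) rather than clamped.
* A model term with zero variance in the data (nobody pruned, say) is a
  hard error before sampling starts.
* Zero-variance trait series cannot define a standardization (error);
  degenerate posterior cases (identical groups in the reserve test,
  all-equal growth in a bin) return well-defined zero-width results.

## Problem sizes in the shipped checks

The automated checks run reduced-scale versions of the recovery
experiments: 2 chains × 2,400--4,000 iterations for replicate fits (20
replicates for coverage-style checks, 5 for selection), and 8--64
replicates × 4 chains × 6,000 iterations in the acceptance script, sizes
at which the Monte-Carlo error of each seed-averaged quantity is small
against its stated tolerance. All are the package's own design choices for
routine verification; the full-size defaults (4 × 20,000) remain the
recommended analysis settings.

## Known limitations

* The sampler is random-walk based; posteriors with strong curvature or
  high-dimensional covariate sets would benefit from gradient-based
  samplers the package deliberately does not include.
* WAIC is computed from thinned draws; its Monte-Carlo error (a fraction
  of a deviance unit) is negligible against the adoption threshold but not
  zero.
* The zero-cost threshold is a point-estimate transform; its posterior
  uncertainty can be obtained by applying `zero_cost_wd()` per draw, which
  the package leaves to the user.
* Selection consistency at the published interaction magnitude is
  intrinsically limited (see *Forward selection* above); this is a
  property of the estimation problem, not of the implementation.
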