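# lookhab

Additive and multiplicative probabilistic models of infant looking times
in fixed-trial habituation experiments.

## The problem

In a habituation experiment an infant watches the same stimulus for `d`
trials and a novel *test* stimulus afterwards; the response is the looking
time (LT) per trial, a positive duration in seconds. Standard analyses
assume LTs are additive and normal, but durations are plausibly
multiplicative: an effect protracts looking by, say, 10 percent rather
than by a fixed number of seconds. `lookhab` implements a model space for
choosing between these views and fits it with a built-in gradient-based
No-U-Turn sampler:

* **Five looking-time families** `D(z, σ)` with support on the positive
  reals — truncated normal (`N`), truncated normal with exponential mean
  (`E`), lognormal (`L`), Weibull (`W`, shape `σ`, scale `e^z`), gamma
  (`G`, shape `σ`, scale `e^z`).
* **Three time structures** for the habituation state of infant `i`:
  trend `z_it = α_i + β_i t + γ_i [t > d_i]`, quadratic
  `z_it = α_i + β_i (t − δ)² + γ_i [t > d_i]`, and autoregressive
  `z_i1 = α_i`, `z_it = r(y_i,t−1) + β_i + γ_i [t − 1 = d_i]`.
* **Two pooling schemes** — separate per-infant fits, or a hierarchical
  (partial-pooling) model with group-level means by stimulus contrast,
  age cohort and habituation-trial count:
  `α_i ~ N(μ^α_b + μ^α_c, σ^α)`, `β_i ~ N(μ^β_b + μ^β_c, σ^β)`,
  `γ_i ~ N(μ^γ_b + μ^γ_c + μ^γ_d, σ^γ)` (or one `μ^γ_{b,d}` per
  contrast-by-trial-count cell in the interaction layout).

Models are addressed by three-letter codes — `GTP` = gamma, trend,
partial pooling; `NTN` = truncated normal, trend, no pooling — and
compared by data log-likelihood at the posterior medians,
posterior-predictive mean absolute error in seconds, and censored
fifth-trial prediction. Population-level utilities include an omnibus
ANOVA on per-infant estimates, parameter-correlation tables with
Fisher-transformation null bands, and the analytic Fisher-information
parameter correlations of each family (for the gamma family
`1/sqrt(σ·ψ′(σ))`, ≈ 0.89 at σ = 2.1; ≈ 0.31 for the Weibull, independent
of σ). A synthetic-data generator reproduces the factorial design of a
301-infant habituation study (3 contrasts × 3 age cohorts × 4
habituation-trial counts, unbalanced cells, dropout and a
"fewer than three test trials" exclusion rule), so the entire pipeline is
testable end to end.

## Worked example

```r
library(lookhab)

# a study-shaped synthetic dataset at about 60 infants
cells <- study_cell_sizes()
cells$n <- pmax(1L, round(cells$n * 60 / 301))
data <- generate_dataset(generator_config(cell_sizes = cells, seed = 7))
ex <- apply_exclusion(data)       # the "< 3 test trials" rule
ex$report$exclusion_rate
#> [1] 16.12903

# fit the gamma-trend partial-pooling model (scaled-down sampler preset)
fit <- fit_partial_pooling(model_spec("G", "T", "partial"), ex$data,
                           sampler_config(seed = 1))
fit
#> <lt_posterior> GTP - 235 variables, 4000 retained draws, 4 chains
#>   converged: TRUE (max R-hat 1.009) - divergent transitions: 122

# main effect of age cohort on the slope, in percent change per trial
subset(main_effects_summary(fit), parameter == "beta" & factor == "cohort")
#>    parameter factor group    unit  2.5%   25%    50%   75% 97.5%
#> 10      beta cohort    4M percent -21.4 -15.9 -13.10 -9.92 -3.72
#> 11      beta cohort    7M percent -19.9 -13.5  -9.88 -6.30  1.46
#> 12      beta cohort   10M percent -12.7  -5.8  -2.15  1.59  9.23
```

The slope rows say that under the multiplicative gamma model the 4-month
cohort's looking times decrease by about 13 percent per trial (median,
with a 95 percent interval from −21 to −4), while the 10-month cohort
shows no reliable decrease in this synthetic sample. The generator's own
mean slope is −7 percent per trial, the value for which ten trials are
needed to reach the common 50-percent habituation criterion:

```r
trials_to_criterion(0.07, 0.5)
#> [1] 10
retained_draws(sampler_config("full"))    # full preset: 6 chains, thin 10
#> [1] 2400
```

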