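---
title: "Probabilistic models of infant looking times: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic models of infant looking times: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lookhab)
```

## The modelling problem

In a fixed-trial habituation experiment an infant watches the same stimulus
on trials $1, \dots, d$ and a novel test stimulus from trial $d + 1$ on.
The response is the looking time (LT) per trial, a positive duration in
seconds. `lookhab` models the LT of infant $i$ on trial $t$ as a draw from
a two-parameter distribution $\mathcal D(z_{i,t}, \sigma_i)$, where
$z_{i,t}$ is a latent *habituation state* and $\sigma_i$ a per-infant
nuisance parameter. The package crosses

* **five families** $\mathcal D$ — truncated normal (N), truncated normal
  with exponential mean (E), lognormal (L), Weibull (W), gamma (G) — with
* **three time structures** — trend
  $z_{i,t} = \alpha_i + \beta_i t + \gamma_i [t > d_i]$, quadratic
  $z_{i,t} = \alpha_i + \beta_i (t - \delta)^2 + \gamma_i [t > d_i]$ with a
  shared peak $\delta$, and autoregressive
  $z_{i,1} = \alpha_i$, $z_{i,t} = r(y_{i,t-1}) + \beta_i +
  \gamma_i [t - 1 = d_i]$ — and
* **two pooling schemes** — separate per-infant fits (no pooling) and a
  hierarchical model (partial pooling) in which
  $\alpha_i \sim \mathcal N(\mu^\alpha_{b_i} + \mu^\alpha_{c_i},
  \sigma^\alpha)$ and likewise for $\beta_i$ and $\gamma_i$, with
  $b_i$ the stimulus-contrast condition, $c_i$ the age cohort and (for
  $\gamma$) $d_i$ the habituation-trial count.

For the N family $z$ is the mean LT in seconds and effects are additive.
For the four multiplicative families $z$ acts on the log scale and a change
$z_\delta$ is displayed as $100(e^{z_\delta} - 1)$ percent
(`percent_change()`). The W and G families are parametrized with scale
$e^z$ and shape $\sigma$; the truncated families include the normalizer
$\Phi(\text{mean}/\sigma)$ so that all five log-likelihoods are directly
comparable. The lognormal is defined by $\log y \sim \mathcal N(z, \sigma)$
— the only reading with positive support.

## Parameters and their interpretation

| parameter | meaning | units |
|---|---|---|
| $\alpha_i$ | initial habituation state (offset) | s (N, E) or log-s |
| $\beta_i$ | change per trial (slope); $100(e^\beta - 1)$ percent per trial for multiplicative families | per trial |
| $\gamma_i$ | dishabituation: state shift on test trials | as $\alpha$ |
| $\delta$ | trial of peak LT (quadratic only), shared across infants | trials |
| $\sigma_i$ | residual scale (N, E, L) or shape (W, G) | family-specific |

A per-trial multiplicative decrease of 7 percent corresponds to
$\beta = \log 0.93 \approx -0.0726$. Under deterministic 7-percent decay,
ten trials are needed to halve the initial LT (`trials_to_criterion(0.07,
0.5)`), and 13 trials when the criterion compares running averages of three
trials (`running_average_criterion_trials(0.07, 0.5, 3)`).

## Priors

The hierarchical model needs priors; the package uses weakly-informative
defaults, all configurable through `lt_priors()` and recorded in each
posterior object:

* population means (and the per-infant parameters of no-pooling fits):
  $\mathcal N(0, 10)$ on the native scale — seconds for N/E, log-seconds
  otherwise;
* population scales $\sigma^\alpha, \sigma^\beta, \sigma^\gamma$ and any
  unpooled $\sigma_i$: half-normal$(0, 5)$;
* nuisance parameters are pooled lognormally by default,
  $\log \sigma_i \sim \mathcal N(\mu^\sigma, \tau^\sigma)$, following the
  precedent of pooling all parameters including the nuisance ones;
* the quadratic peak: $\delta \sim \mathcal N(1, 2)$. Constrained variants
  of such models are known to collapse onto $\delta \approx 1$ (a
  monotone decrease), so the prior centers there while leaving the data
  free to move it.

The additive decomposition $\mu_b + \mu_c$ is deliberately redundant — an
overall constant can move between the blocks — and is regularized only by
the zero-centered priors. Reports therefore display identified sums: a
group's displayed value is its own mean plus the draw-wise average of the
other factor's means (`main_effects_summary()`). Any other convention for
the unidentified constant would shift all groups of one factor equally and
leave group differences untouched.

## Sampling

Models are fitted by a built-in No-U-Turn sampler (dynamic Hamiltonian
Monte Carlo with slice-based tree selection, dual-averaging step-size
adaptation targeting 0.8 acceptance, and a diagonal mass matrix estimated
from the middle half of warm-up). Two details matter for efficiency and
correctness:

* **Non-centered parametrization.** Infant-level effects are sampled as
  standardized raws, $\alpha_i = \mu^\alpha_{b_i} + \mu^\alpha_{c_i} +
  \sigma^\alpha \tilde\alpha_i$ with $\tilde\alpha_i \sim \mathcal N(0,1)$,
  which removes the funnel between the scales and the effects at the small
  per-infant trial counts typical for this design.
* **Rotated population blocks.** The redundant mean decomposition creates a
  long prior-only ridge (e.g. adding $k$ to every $\mu_b$ and subtracting
  it from every $\mu_c$). The sampler works in an orthonormal rotation of
  each mean block that isolates these flat directions into single
  coordinates. Because the iid normal prior is rotation-invariant the model
  is unchanged, but trajectories no longer need to traverse the ridge;
  draws are rotated back before reporting.

Two sampler presets exist (`sampler_config()`): the full preset — six
chains of 10,000 iterations, 6,000 warm-up, thinning 10, retaining
$6 \cdot (10{,}000 - 6{,}000)/10 = 2{,}400$ draws — and a scaled-down
default (four chains of 2,000, 1,000 warm-up, no thinning) used for
simulation studies and the test suite. Convergence is gated per variable at
split-$\hat R < 1.1$, computed on retained draws; non-converged fits are
returned with `converged = FALSE` and excluded from comparison summaries
rather than silently dropped. Initial values are centered on a
data-informed location (mean LT or mean log LT) with per-chain jitter;
divergent transitions are counted and reported. Degenerate inputs — zero
residual variance, a constant posterior — yield an `NA` $\hat R$ with a
warning rather than a spurious pass.

## The synthetic-data generator

`generate_dataset()` emulates the factorial design of a fixed-trial
habituation study: 3 contrast conditions (luminance, color, orientation)
$\times$ 3 age cohorts (4M, 7M, 10M; half-open age boundaries at 117, 165,
255, 339 days, upper edges belonging to the older cohort) $\times$ 4
habituation-trial counts (1, 3, 5, 7), with the unbalanced cell sizes of
the study sample (301 infants, `study_cell_sizes()`) as the default.
Defaults are calibrated once to the study conditions:

* gamma-trend generating model, shape hyper-center 2.1;
* mean slope $\log 0.93$ (a 7 percent decrease per trial);
* initial mean LTs of 3.7 s (luminance) and 5 s (color, orientation); the
  offset defaults include the lognormal mean correction
  $(\tau^2 + \sigma_\alpha^2 + \sigma_\beta^2)/2 \approx 0.0655$ so the
  *arithmetic* mean matches the target;
* dishabituation strongest for luminance (0.35), weak-to-negative for
  orientation ($-0.05$), with an early-vs-late split of $\mu^\gamma_d$
  equal to a latent contrast of $0.192$, i.e. 21.2 percent;
* between-infant scales $\sigma^\alpha = 0.3$, $\sigma^\beta = 0.03$,
  $\sigma^\gamma = 0.15$ and $\log\sigma_i \sim \mathcal N(\log 2.1, 0.2)$
  — chosen as plausible magnitudes relative to the group effects, so that
  shrinkage is material but does not dominate;
* a per-trial geometric dropout hazard of 0.029 after trial 1, which
  reproduces a session-exclusion rate of roughly 16 percent under the
  "fewer than three test trials" rule (`apply_exclusion()`). The hazard
  subsumes the gaze-level abandonment rule of a real eye-tracking session.

The generator does **not** emulate gaze-level artifacts (attention
catchers, eye-tracker lights, fixation classification), within-session
non-stationarity beyond the chosen time structure, or any correlation
between the per-infant parameters — they are drawn independently. Passing
tests therefore demonstrate that the pipeline recovers what it assumes, on
data of the study's shape; they cannot validate the behavioral assumptions
against real infants.

## Evaluation metrics

`loglik_at_medians()` scores a model by the data log-likelihood at the
per-variable marginal posterior medians. `mean_absolute_error()` draws
(by default) 1,000 predictive samples per trial at the median parameters
and reports the per-infant mean absolute deviation in seconds, summarized
across infants by the median, the 25–75 and the 2.5–97.5 percentile bands.
`censored_prediction()` refits with the fifth trial removed from every
qualifying infant's likelihood and reports the held-out log-density at the
medians plus the absolute error at trial 5 — both the error of the
posterior-predictive mean and the mean draw-wise error, since either
convention is defensible. The censored refit is restricted to the trend
and quadratic structures: the autoregressive state at trial 5 would
require the censored observation itself, so the structure declares itself
inapplicable instead of imputing.

## Population analyses

`anova_table()` runs the omnibus ANOVA on per-infant medians from
converged no-pooling fits, with Type-II sums of squares for the unbalanced
design and a configurable $\alpha = 0.05$ star flag (neither is dictated
by the analysis itself; Type II is the conventional choice when
interactions are weak). `correlation_table()` gives the six Pearson
correlations between per-infant median estimates, with
`fisher_ci_halfwidth()` supplying the Fisher-transformation null band.
`lt_fisher_information()` and `lt_parameter_correlation()` provide the
asymptotic counterpart: the correlation implied by the inverse expected
information — zero for N, E and L, $\approx 0.31$ for the Weibull
independent of $\sigma$, and $1/\sqrt{\sigma\,\psi'(\sigma)}$ for the
gamma (0.89 at $\sigma = 2.1$). The function returns the magnitude; the
signed estimate correlation is positive for W and negative for G, where
shape and scale trade off against the well-determined mean
$\sigma e^z$.

`dishabituation_contrast()` evaluates the early-vs-late contrast
$(\gamma_{B5} + \gamma_{B7} - \gamma_{B1} - \gamma_{B3} + \gamma_{C5} +
\gamma_{C7} - \gamma_{C1} - \gamma_{C3})/4$ per draw on the latent scale
and percent-transforms before taking quantiles (the transform is monotone,
so order statistics commute).

## Numerical and design choices

* Trial indices are 1-based; the Iverson brackets use strict (`t > d`) and
  equality (`t - 1 = d`) comparisons exactly as written above.
* The running-average criterion compares trials $1..w$ against
  $t-w+1..t$ under $LT_t \propto (1-\rho)^{t-1}$; with $w = 3$ and
  $\rho = 0.07$ this yields 13 trials. Other window conventions (e.g.
  non-overlapping blocks) give slightly different counts, which is why the
  window convention is explicit and selectable.
* Fisher information for the truncated families is computed for the
  untruncated normal; the truncation correction is negligible when
  $\text{mean}/\sigma > 3$, which holds for realistic looking times.
* Quantiles use R's default type-7 rule everywhere.
* `rhat()` is the split-chain variant; a trending chain is detected
  through its half-means, so permuting draws within a chain can change the
  value — the documented price of the split formulation.
* Posteriors serialize to long-format CSV (chain, iteration, variable,
  value) with a JSON diagnostics sidecar; datasets to a seven-column CSV
  with a JSON metadata sidecar carrying the seed and generator
  configuration.

## Problem sizes used by the test suite

The simulation-based checks run at deliberately modest sizes chosen to
exercise the study's design shape: hierarchical parameter recovery uses 20
replications of a 60-infant study-shaped design under the scaled-down
sampler preset, with pooled 95-percent-interval coverage of the displayed
population means assessed across all means and replications;
matched-family self-consistency and the partial-vs-no-pooling prediction
comparison use 10 replications each (60 and 40 infants); the
Monte-Carlo score-covariance check uses $2 \times 10^5$ draws per family;
the maximum-likelihood correlation check uses 500 replicates of $n = 200$.

## Known limitations

* In-sample data log-likelihood at the posterior medians does not identify
  the generating family at the study's trial counts: in the package's own
  simulations the Weibull trend model attains the best in-sample fit on
  gamma-generated data in every replication, under both pooling schemes,
  while for iid samples at a fixed state the gamma (true) family already
  wins at seven observations. The reversal is a property of the
  four-parameter per-infant fit evaluated at plug-in medians — which is
  why the censored-trial predictive metrics exist and should carry the
  model choice.
* Correlation tables computed from hierarchically shrunk medians are
  clustered by the design's group structure: when a parameter's
  between-infant spread is small relative to its posterior uncertainty
  (the slope, with $\sigma^\beta = 0.03$), infant medians collapse onto
  roughly the dozen group means, the effective sample size approaches the
  number of design cells, and the iid Fisher null band is
  anti-conservative for them — the simulated tables land well outside the
  band even though the generating correlations are zero.
* With 4–10 trials per infant, the per-infant likelihood of the gamma and
  Weibull shape is strongly right-skewed; hierarchical posteriors of the
  nuisance location drift above the generating value at realistic sample
  sizes, and the correlated offset posteriors widen accordingly. This is a
  property of the model class at these trial counts, visible in the
  recovery simulations, not a sampler artifact (the posterior agrees with
  an independent random-walk sampler on the same density).
* The quadratic structure shares one $\delta$ across infants;
  infant-specific peaks are not supported (hierarchical fits of that
  variant are known not to converge at these data sizes).
* No model averaging, information criteria, or variational fits: model
  comparison is by the three metrics above.
* The partial-pooling design matrix expects the study's factor levels
  (3 contrasts, 3 cohorts, habituation-trial counts in {1, 3, 5, 7});
  no-pooling fits accept any positive trial counts.
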