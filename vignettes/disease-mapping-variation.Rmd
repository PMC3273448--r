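---
title: "Models and methods: small-area variation and shared component disease mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: small-area variation and shared component disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealvar)
```

## The problem

Health-services researchers study geographic variation in utilization —
hospital admissions, surgery rates — across small areas.  Two questions
recur: *how much* of the area-to-area variation is systematic rather
than Poisson noise, and *where* is utilization systematically high or
low?  When the same outcome is observed for two related groups (here,
men and women of the same population), a third question appears: how
much of the geographic pattern is *shared* between the groups, and
where do they *diverge*?

`arealvar` answers these at three levels of model complexity:

1. **Classical small-area variation analysis (SAVA)** — per-area
   utilization ratios and scalar statistics of variation, assuming
   independent areas.
2. **The Besag–York–Mollié (BYM) model** — a hierarchical Poisson model
   per group that splits log-relative-risk variation into spatially
   structured and unstructured components.
3. **The shared component model (SCM)** — a joint model for both groups
   that partitions variation into a shared spatial surface and
   group-specific remainders.

Throughout, area $i$ has observed count $o_i$, population at risk
$N_i$, and expected count $e_i$ from single-stratum indirect
standardization: $e_i = r N_i$ with $r = \sum o_i / \sum N_i$ the
whole-region rate, computed separately per group.  Age standardization
is deliberately out of scope: the intended use restricts to a
homogeneous age band and standardizes by group only.  Areas with zero
population (hence $e_i = 0$) in a stratum are rejected rather than
imputed.

## Classical statistics

With $\mathrm{IUR}_i = o_i / e_i$ (the MLE of the risk $\rho_i$ under
the saturated model $o_i \sim \mathrm{Poisson}(e_i \rho_i)$), exact
intervals use the Poisson–gamma relationship (Garwood):
lower $= F^{-1}_{\Gamma(o_i)}((1-\gamma)/2)/e_i$ (zero when $o_i = 0$),
upper $= F^{-1}_{\Gamma(o_i+1)}(1-(1-\gamma)/2)/e_i$.  These intervals
are conservative: realized coverage is at or above the nominal level,
which the test suite checks by simulation.

Five statistics of variation are provided, on per-area crude rates
$r_i = o_i/N_i$ or on $(o_i, e_i)$:

* **EQ** (extremal quotient): the ratio of the 95th to the 5th
  percentile of $r_i$.  The percentile rule is linear interpolation
  between order statistics (`quantile` type 7) — the most common
  convention; any fixed rule would do, but it must be stated because EQ
  values are not comparable across rules.
* **CV** and **CV$_w$**: sample coefficient of variation ($n-1$
  denominator) and its population-weighted version (weights normalized
  to sum to one, standard deviation about the weighted mean).
* **SCV** (systematic component of variation, McPherson):
  $\frac1n\sum_i[((o_i-e_i)/e_i)^2 - 1/e_i]$, reported on the natural
  scale (not $\times 100$).  The $1/e_i$ term subtracts the expected
  Poisson contribution, so SCV estimates between-area variation only
  and can be negative for sub-Poisson data.
* **EB**: a Marshall-type method-of-moments estimate of the
  between-area variance of the risks,
  $\max\!\left(0, \frac{\sum_i e_i (r^{(e)}_i - \bar r)^2}{\sum_i e_i}
  - \frac{\bar r\, n}{\sum_i e_i}\right)$ with $r^{(e)}_i = o_i/e_i$
  and $\bar r = \sum o_i / \sum e_i$.  Several EB-style estimators
  circulate in this literature; the moment estimator with truncation at
  zero was chosen as the standard, simplest member of the family, and
  the implementation is tested against its own literal transcription
  rather than against any published table.

Confidence intervals for all five come from a parametric bootstrap
(default 1,000 replicates): $o_i^\ast \sim \mathrm{Poisson}(e_i \cdot
o_i/e_i)$ per replicate, percentile intervals, fixed seed.  The
bootstrap conditions on the estimated rates; it captures sampling noise
around them, not model uncertainty.

## The BYM model

Per group, $o_i \sim \mathrm{Poisson}(e_i\rho_i)$ and

$$\log \rho_i = \alpha + u_i + v_i,$$

with $u$ an intrinsic CAR (ICAR) field — $u_i \mid u_{-i} \sim
N(\bar u_{\partial i},\, 1/(\tau_u d_i))$ over the neighbourhood graph —
and $v_i \sim N(0, 1/\tau_v)$ exchangeable.  The intercept $\alpha$ is
flat; both precisions carry $\mathrm{Gamma}(0.5, 0.0005)$ hyperpriors
(stated for the SCM's precisions; adopted for BYM too for internal
consistency).

The headline summary is the **spatial fraction**
$s_u^2/(s_u^2+\sigma_v^2)$, computed per posterior draw with
$s_u^2 = \sum_i (u_i-\bar u)^2/(n-1)$ the *empirical marginal* variance
of the ICAR field (the conditional variance $1/\tau_u$ is not
comparable to $\sigma_v^2$ and is never used in the fraction).  The
"unstructured variance" reported is the posterior of
$\sigma_v^2 = 1/\tau_v$ itself, not the empirical variance of the $v$
draws; the two differ by shrinkage, and the parameter is the
convention the fraction formula implies.  All summaries are posterior
medians with central 95% intervals.  Per-area exceedance probabilities
$\Pr(\rho_i > 1 \mid \text{data})$ are reported with a 0.95 flagging
threshold for probability maps.

### A caution on the spatial/unstructured split

The likelihood constrains only $u_i + v_i$; the split between $u$ and
$v$ is informed by the priors (smoothness vs exchangeability) alone.
This makes the spatial fraction a *soft* quantity: when a realized
exchangeable field happens to be mildly spatially autocorrelated —
which is common on lattices of ~180 areas — the posterior attributes
that part to the spatial component, and the fraction's posterior median
can sit far from the generative variance ratio even when the sampler
has converged.  The package's seeded recovery experiments measure
exactly this dispersion; interval summaries of the fraction should
always be reported alongside the median.

## The shared component model

For men ($g=1$) and women ($g=2$) jointly,
$o_{gi} \sim \mathrm{Poisson}(e_{gi}\rho_{gi})$ and

$$\log\rho_{1i} = \alpha_1 + \delta\lambda_i + \varphi_{1i},
\qquad
\log\rho_{2i} = \alpha_2 + \lambda_i/\delta + \beta_i + \varphi_{2i}.$$

$\lambda$ is the shared spatial surface (ICAR), $\beta$ the
women-specific spatial surface (ICAR), $\varphi_g$ exchangeable
residuals, and $\delta > 0$ the scaling that allocates the shared
gradient between the groups ($\delta = 1$: symmetric loading).  Which
group carries $\beta$ and the $\delta$-vs-$1/\delta$ direction are
fixed conventions of the model, not options: swapping the datasets maps
$\delta \mapsto 1/\delta$ and moves the specific field to the other
group, which the test suite checks.

Priors: $\alpha_1, \alpha_2$ flat; $\log\delta \sim N(0,
\text{precision } 0.2)$ (i.e. variance 5; the precision convention is
used for all normal priors here, and the value is configurable via
`delta_prior()` — a bounded $\mathrm{Uniform}(0.5, 2)$ alternative on
$\delta$ itself is provided); all four precisions
$\mathrm{Gamma}(0.5, 0.0005)$.  For sensitivity analysis,
`precision_hyperprior()` offers $\mathrm{Gamma}(0.01, 0.01)$
(equivalent to inverse-gamma(0.01, 0.01) on the variance),
$\mathrm{Uniform}(0, 100)$ on the standard deviation, and a
half-normal (precision 0.01) on the standard deviation; `scm_priors()`
can also switch $\lambda$ or $\beta$ to exchangeable.  With *both*
fields exchangeable the model is only weakly identified against the
$\varphi$ fields, and the fit warns.

**Variance partition.**  Per draw, the empirical across-area variances
of each additive log-risk term are computed: men
$V(\delta\lambda), V(\varphi_1)$; women $V(\lambda/\delta), V(\beta),
V(\varphi_2)$.  Fractions are each term's share of the group total, so
they sum to one within every draw by construction.  The women-specific
share is reported both in total and split into its spatial and
unstructured parts.  The "common spatial variance" reported is the
posterior of $V(\lambda)$ (the empirical variance of the shared field),
consistent with defining all fractions through empirical variances.

**Component maps.**  $\Pr(e^{\lambda_i} > 1)$ and
$\Pr(e^{\beta_i} > 1)$ per area, with posterior medians of
$e^{\lambda}$ and $e^{\beta}$, support shared and discrepant
choropleths; the discrepant map is the model's main practical payoff —
it flags areas where latent factors act differently on the two groups.

## Posterior computation

All models are fitted by single-site Metropolis-within-Gibbs, the
WinBUGS-era approach these models were designed around, implemented in
C++:

* Random-effect sites and intercepts: Gaussian random-walk Metropolis.
  Proposal scales adapt by Robbins–Monro (target acceptance 0.4,
  window of 100 sweeps, step $1/\sqrt{k}$) **during burn-in only** and
  are frozen afterwards, so kept draws satisfy detailed balance.
* Precisions with gamma hyperpriors: conjugate Gibbs,
  $\tau \mid \cdot \sim \mathrm{Gamma}(a + n_\mathrm{eff}/2,
  b + Q/2)$ with $Q$ the ICAR pairwise quadratic form (or sum of
  squares for exchangeable fields).  The sd-scale hyperpriors are
  non-conjugate and use random-walk Metropolis on $\log\tau$ with the
  appropriate Jacobian.
* $\delta$: random walk on $\log\delta$ under the log-normal prior;
  random walk on $\delta$ with rejection at the bounds under the
  uniform prior.
* **Identifiability.**  ICAR fields are improper: after every sweep
  each field is re-centered to mean zero per connected component, with
  the absorbed constant folded exactly into the corresponding flat
  intercept(s) ($\lambda$'s constant enters both intercepts, scaled by
  $\delta$ and $1/\delta$).  The model keeps one flat intercept per
  connected component of size $\ge 2$.  Degree-zero areas, where the
  ICAR conditional is undefined, receive an exchangeable
  $N(0, 1/\tau_u)$ spatial effect and share one pooled intercept; as a
  consequence the ICAR rank used in the precision update is
  $n_\mathrm{eff} = n - \#\{\text{components of size} \ge 2\}$.
  $\varphi$ fields are proper and are not centered.
* **Exchange move (BYM).**  Because the likelihood sees only
  $u_i + v_i$, site updates alone mix the spatial/unstructured split
  very slowly.  An extra sweep proposes $(u_i + d, v_i - d)$, which
  leaves the likelihood untouched and is accepted on the prior ratio
  alone; this move cut split-chain $\hat R$ for the variance
  components from $>3$ to $\approx 1$ at the default schedule.

**Schedules.**  The production schedule (`production_schedule()`) is a
burn-in of 50,000 followed by 100,000 iterations keeping every 10th.
The default (`mcmc_config()`) is the same shape at 1/10 scale — burn-in
5,000, then 10,000 keeping every 10th, two chains — which the
convergence diagnostics show is adequate on 180-area lattices and keeps
a full fit in the low seconds.  Chains are seeded as
`seed + chain - 1` with over-dispersed random initial values; results
are bit-for-bit reproducible given the configuration.

**Diagnostics and model comparison.**  Convergence is monitored with
the split-chain potential scale reduction factor on the intercepts,
variance summaries, $\delta$, deviance and all per-area log risks
(reported as a maximum); any $\hat R > 1.1$ flags the fit (at least two
chains are required).  DIC uses $p_D = \bar D - D(\hat\theta)$ with
$D$ the Poisson deviance *without* the saturated term, matching the
WinBUGS convention, and $\hat\theta$ the posterior mean of the fitted
means; DIC values are therefore comparable between fits of this
package only.  `compare_dic()` totals the two independent per-group
BYM DICs against the joint SCM DIC and also reports the mean posterior
standard deviation of the log relative risks per model — the precision
gain of joint modelling.

## The synthetic-data generator

`simulate_scm()` / `simulate_bym()` draw data forward from exactly the
models above, on a rook-neighbourhood lattice (default 12 × 15 = 180
areas, matching the scale of a national healthcare-area map).  Default
parameters emulate a national study of chronic-disease admissions in
an elderly population:

| parameter | default | rationale |
|---|---|---|
| populations per area | log-normal, mean 6,800 (men) / 10,900 (women), sdlog 0.7 | thousands-to-tens-of-thousands at risk per gender, right-skewed as real area populations are |
| baseline rates | 0.214 (men) / 0.140 (women) | ~21 and ~14 admissions per 100, the scale of chronic-disease admissions in the elderly |
| shared spatial variance | 0.08 | dominant shared surface |
| women-specific spatial variance | 0.004 | small structured discrepancy |
| unstructured variances | 0.0005 / 0.0015 | near-negligible residual heterogeneity |
| $\delta$ | 1 | symmetric loading |

With these defaults the realized women shared fraction is ~0.94 across
seeds — a regime where the shared surface dominates but the specific
components remain detectable.

ICAR fields are sampled in the eigenbasis of the graph Laplacian (null
space excluded) and **rescaled so the empirical marginal variance
equals the target exactly**.  This matters: the fractions the models
estimate are defined through empirical variances, so the simulation
controls the estimand itself rather than a prior parameter that only
loosely determines it.  Forward sampling is restricted to connected
lattices.  The returned dataset carries expected counts recomputed by
indirect standardization from the realized observations — what an
analyst would construct — while the truth record keeps the generative
expecteds, every latent field, and the realized variances and
fractions.

What the generator does *not* emulate: age structure and age
standardization, irregular area geometries (degree distributions of
real maps are more skewed than a lattice's), islands, overdispersion
beyond the modelled log-normal risk variation, and any within-area
correlation between the genders' populations.  Passing recovery tests
on these simulations therefore shows the estimators are correct *under
the model*, not that the model is adequate for any particular real
dataset.

## Problem sizes used in tests

The test suite runs recovery experiments at the full 180-area scale
with the default (1/10-scale) schedule: 10 seeds for the BYM fraction,
20 for SCM recovery and $\delta$ coverage, 10 for the DIC comparison,
and a three-configuration hyperprior grid; smaller lattices (25–36
areas) and shorter chains are used for smoke and invariance tests.
These sizes were chosen so the whole suite completes in a few minutes
while keeping the experiments at the data scale the defaults emulate.

## Known limitations

* The BYM spatial fraction is weakly identified (see above); its
  posterior median has substantial seed-to-seed dispersion around the
  generative value even with a converged sampler.
* Single-site updates mix slowly for strongly coupled fields; the
  exchange move addresses the dominant BYM direction, but very long
  chains remain advisable for publication-grade runs
  (`production_schedule()`).
* DIC with the plug-in at the posterior mean can misbehave for very
  skewed posteriors (negative $p_D$ is reported with a warning rather
  than hidden).
* No covariates (ecological regression), no more-than-two outcomes, no
  space–time extension, and no derivation of adjacency from polygon
  geometry — adjacency must be supplied or simulated.
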