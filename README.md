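# arealvar

Geographic variation in areal count data: classical small-area
variation statistics, Besag–York–Mollié (BYM) disease mapping, and the
two-outcome shared component model (SCM), with a synthetic-data module
that generates lattice datasets from the same generative models with
known variance structure.

## Who this is for

Health-services and spatial-epidemiology researchers with per-area
event counts (hospital admissions, procedures, cases) and populations
at risk for two related outcomes — typically men and women — who want
to quantify how much area-to-area variation is systematic, map where
risk is high, and partition the geographic pattern into a component
*shared* by the two outcomes and components *specific* to each.

## The models

With observed counts `o_i`, populations `N_i` and indirectly
standardized expected counts `e_i = N_i · Σo/ΣN` (per outcome):

* **SAVA** — indirect utilization ratios `IUR_i = o_i/e_i` with exact
  Poisson (Garwood) intervals, and the statistics of variation EQ
  (95th/5th percentile ratio), CV, weighted CV, SCV
  (`mean(((o−e)/e)² − 1/e)`) and the EB moment estimate of
  between-area risk variance, all with parametric-bootstrap intervals.
* **BYM** — `o_i ~ Poisson(e_i ρ_i)`,
  `log ρ_i = α + u_i + v_i`, `u` intrinsic CAR on the adjacency graph,
  `v` exchangeable; reports the spatial fraction
  `s_u²/(s_u² + σ_v²)` (with `s_u²` the empirical marginal variance of
  `u`) and exceedance probabilities `Pr(ρ_i > 1)`.
* **SCM** — jointly,
  `log ρ_1i = α₁ + δλ_i + φ_1i` and
  `log ρ_2i = α₂ + λ_i/δ + β_i + φ_2i`:
  a shared spatial surface `λ` scaled by `δ`, a second-outcome-specific
  spatial surface `β`, exchangeable residuals `φ`.  Reports the
  per-outcome variance partition (shared vs specific, the specific part
  split into spatial and unstructured), `δ`, exceedance maps for
  `e^λ` and `e^β`, and DIC against the two independent BYM fits.

Fitting is Metropolis-within-Gibbs MCMC (C++ core) with conjugate
precision updates, per-component sum-to-zero centering of ICAR fields,
burn-in-only proposal adaptation, split-chain R-hat diagnostics and
WinBUGS-convention DIC.  See the vignette
(`vignettes/disease-mapping-variation.Rmd`) for the full model and
sampler account.

## Worked example

Simulate a 180-area paired dataset at the default study scale
(admission rates 21.4 / 14.0 per 100, shared spatial variance 0.08,
women-specific spatial variance 0.004, δ = 1) and fit the shared
component model:

```r
library(arealvar)

sim <- simulate_scm(simulation_params(seed = 42))
sim$dataset
#> Paired areal dataset: 180 areas
#>   men:    268021 events / 1,184,220 at risk
#>   women:  274030 events / 1,858,813 at risk

fit <- fit_scm(sim$dataset, config = mcmc_config(seed = 42))
fit
#> Shared component model fit: 180 areas, 2 chains
#>   shared fraction: men 99.1% (97.6, 99.8), women 94.0% (92.2, 95.7)
#>   delta: 0.986 (0.957, 1.016)
#>   DIC 3852.29 (pD = 299.85)

round(fit$partition$summary[1:6, ], 4)
#>                             median ci_low ci_high
#> men_shared                  0.9912 0.9756  0.9981
#> men_specific                0.0088 0.0019  0.0244
#> women_shared                0.9400 0.9217  0.9571
#> women_specific              0.0600 0.0429  0.0783
#> women_specific_spatial      0.0443 0.0201  0.0646
#> women_specific_unstructured 0.0143 0.0022  0.0400
```

Reading the output: 94.0% (95% CI 92.2–95.7) of the across-area
variance of the women's log relative risks is carried by the shared
surface — against a realized value of 93.1% in this simulation
(`sim$truth$realized_fractions$women_shared`) — with the remaining 6%
split into a spatially structured discrepancy (4.4%) and unstructured
residual (1.4%); `δ` near 1 means the shared gradient loads
symmetrically on both outcomes.  `fit$maps` holds the per-area shared
and discrepant exceedance probabilities for mapping, and
`compare_dic()` quantifies the goodness-of-fit and precision gain over
two independent BYM fits.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/arealvar.R compare --out_dir results-demo --seed 42
Rscript inst/cli/arealvar.R sensitivity --out_dir results-sens --seed 42
```

which writes seeded, fingerprinted tables (variation statistics,
per-area ratios, BYM and SCM summaries, model comparison) into the
output directory; `--counts`/`--adjacency` switch from simulated to
user-supplied data, `--production_schedule` enables the long production
MCMC schedule, and `--config file.yaml` mirrors every flag.

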