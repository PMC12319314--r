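---
title: "Estimating lytic-virus life histories: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lytic-virus life histories: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Lytic viruses of microbial hosts — here modelled on the chloroviruses, large
dsDNA phycodnaviruses that infect freshwater chlorella-like algae — are
characterized by a small set of life-history traits that together determine
their fitness: how fast virions find hosts, how reliably an encounter becomes
a productive infection, how long the infected cell takes to lyse, how many
progeny emerge, and how fast free virions lose infectivity while waiting for
the next host. `virotraits` estimates nine such traits per virus strain from
replicate-level growth and survival assay data, attaches a bootstrap 95% CI
to every estimate, predicts population growth rates from the traits, and
provides the comparative statistics used to ask how trait diversity is
structured across a strain panel.

The nine traits, with units:

| symbol | meaning | units |
|---|---|---|
| `k` | adsorption constant | mL h⁻¹ |
| `d` | depolarization probability per adsorbed virion | – |
| `r` | release probability per depolarized cell | – |
| `mu_l`, `sigma_l` | mean and SD of lysis time | h |
| `b_d` | burst size per depolarized cell | virions |
| `b_r` | burst size per releasing cell | virions |
| `s` | specific infectivity | – |
| `m` | mortality (decay) rate | h⁻¹ |
| `p` | persistent fraction | – |

Two identities tie the set together: `b_d = r * b_r`, and `s = a * d * r`,
where `a` is an auxiliary *attaching fraction* — the fraction of virions
capable of adsorbing at all. The trait list names no attachment symbol;
we introduce `a` as the plateau of the adsorption assay because it makes the
composition of specific infectivity well-defined and identifiable from the
assays: without it, a non-adsorbing subpopulation would silently deflate `d`
or `r` depending on the fitting order.

## Assay models

Each trait is identified by the closed-form expectation of one assay:

* **Adsorption.** Free virions deplete exponentially in the presence of
  hosts at density `H`: `V(t) = v0 * ((1 - a) + a * exp(-k * H * t))`.
  The non-attaching fraction `1 - a` is the late-time plateau. The fit is
  nonlinear least squares on the log scale with the overall scale (`log v0`)
  profiled out analytically; when the fitted plateau is indistinguishable
  from complete adsorption (`a > 0.995`) the model reduces to log-linear
  regression with slope `-k * H`.

* **Depolarization.** At adsorbed multiplicity `MOI`, the fraction of cells
  with at least one depolarizing virion is `1 - exp(-d * MOI)` (Poisson
  multiplicity statistics). The estimator inverts this with counts pooled
  across replicates, because per-replicate counts may be small; the bootstrap
  restores the sampling uncertainty at the cell level.

* **One-step growth.** Infectious centers per depolarized cell decline as
  releasing cells lyse: `IC(t)/D = r * (1 - Phi((t - mu_l)/sigma_l))`, with
  the lysis-time normal left-truncated at zero (a cell cannot lyse before it
  is infected). The plateau is the release probability, the midpoint the mean
  lysis time. Free progeny accumulate as `b_r` per lysed cell, so the final
  yield minus the residual inoculum, per depolarized cell, is `b_d`.

* **Survival.** Decay is biphasic: `S(t) = S0 * (p + (1 - p) * exp(-m * t))`.
  Most virions decay at rate `m`; a persistent fraction `p` resists decay.

* **Growth assay.** Total titer grows exponentially; the observed rate is the
  log-linear slope over a configurable window (default: the full series).

## Growth prediction

The population growth rate `lambda` implied by a trait set solves the lytic
Euler–Lotka characteristic equation

$$ 1 \;=\; s\, b_r \,\frac{kH}{kH + \lambda}\, e^{-\lambda \mu_l}. $$

Read right to left: a virion's progeny count (`s * b_r`, only infectious
virions count), discounted by the race between adsorption at rate `kH` and
removal from the growing cohort at rate `lambda`, delayed by a point lysis
lag `mu_l`. The left side is strictly decreasing in `lambda` on
`(-kH, Inf)`, so the root is unique; we find it by bracketed bisection with
the infinite-host closed form `log(s * b_r) / mu_l` as an upper bound, and
admit negative rates (declining populations) down to `-kH`. The residual of
the characteristic equation at the returned root is checked against `1e-9`.

Design choices here: the lysis delay is a point delay at `mu_l` —
`sigma_l` is deliberately excluded, because the prediction is defined on
exactly the four traits `s`, `k`, `mu_l`, `b_r`; mortality likewise enters
only the comparative trade-off tests, not the prediction. The host density
for predictions is a configuration value (default `1e7` cells/mL, a typical
dense algal culture) reported alongside every prediction. The functional
form sits behind a single function (`predict_growth_rate()`) so an
alternative delay kernel can be swapped without touching the interface.

## Confidence intervals

Every trait carries a nonparametric bootstrap percentile 95% CI
(default `n_boot = 1000`). The resampling unit is the **individual
observation** (ordinary case resampling of each assay table's rows), and the
depolarization counts are resampled at the cell level, which for pooled
counts is exactly binomial resampling. Two alternatives were considered and
rejected for the default:

* *Whole-replicate resampling* respects replicate-level correlation, but
  with the triplicate designs typical of these assays a percentile interval
  built on three exchangeable units is severely anti-conservative (on the
  order of 70–85% coverage at nominal 95%). It remains available as
  `resample = "replicate"` for data where replicate effects are real.
* *Time-stratified observation resampling* preserves the design exactly but
  shrinks the bootstrap variance by the within-stratum factor
  `(n_s - 1)/n_s` — a 2/3 shrinkage at three rows per time point — and
  measurably undercovers. Plain case resampling has the same bias factor
  only globally (`1 - 1/N` at `N` = 27–57 rows per table), which is
  negligible.

The per-strain orchestration (`estimate_profile()`) bootstraps **jointly**:
each iteration resamples all assay tables at once and re-runs every
estimator, so the intervals for derived traits (`s = a*d*r`,
`b_d`, `b_r`) propagate the joint uncertainty of their components rather
than multiplying intervals. The point estimate is guaranteed to lie inside
its own interval (the original fit joins the percentile set if needed, and
the adjustment is flagged).

A trait is flagged **poorly resolved** — and excluded from downstream
comparative analysis — when its CI spans more than two orders of magnitude
(rates, sizes, times), more than 0.8 probability units, or when more than
20% of bootstrap refits fail. The assay data themselves give no such rule,
so this is a package convention chosen to mirror the practice of blanking
unresolvable estimates.

## Numerical choices

* Zero counts on the log scale get no pseudocount; when zeros are present
  the objective switches to Poisson-weighted least squares (profiled-scale
  Poisson deviance).
* The biphasic decay SSE surface is multimodal, so the optimizer is
  multi-started over `m` in {fast log-linear slope, 10x that} crossed with
  `p` in {~0, last/first titer ratio}; a pure-exponential candidate with the
  closed-form slope competes on equal terms, which makes single-phase data
  reduce *exactly* to log-linear regression. Near-ties go to the smaller
  mortality rate.
* `sigma_l` is bounded below by half the median sampling interval: a
  zero-SD lysis-time fit on a coarse grid is indistinguishable from a step
  and would be degenerate.
* Probability-valued traits are clamped to `[0, 1]`, rates and sizes to
  `>= 0`, after fitting on unconstrained transformed scales
  (log / logit), which also keeps the optimizers away from boundaries.
* Burst-size windows are placed from the fitted lysis curve: residual
  inoculum is read before `mu_l - 3 sigma_l`, the final yield after
  `mu_l + 3 sigma_l`; a grid that ends earlier triggers a truncation flag.

## Comparative statistics

* **Fold-range**: `max/min` over resolved, positive estimates.
* **Variance partitioning** by type host: `R² = SS_between / SS_total` on
  point estimates, with a permutation P-value
  (`(count >= observed + 1)/(n_perm + 1)`, default `n_perm = 9999`) rather
  than a parametric F test, because group sizes are small and unbalanced.
* **Predicted vs observed growth**: Spearman rank correlation; exact
  permutation P for `n <= 10`, asymptotic t otherwise.
* **AIC all-subsets selection**: OLS over all 16 subsets of
  `{k, mu_l, s, b_r}`, `AIC = n log(RSS/n) + 2K` with `K` counting the
  intercept and the error variance. The consensus set is the intersection of
  predictor sets over models within 2 AIC units of the best. (This AIC
  differs from the Gaussian log-likelihood version by an additive constant,
  which cancels in every delta.)
* **Trade-off correlations**: weighted Pearson with per-strain weights
  `w_i` proportional to `1/(breadth_x_i * breadth_y_i)` — the
  precision-product rule, down-weighting a strain that is uncertain in
  *either* coordinate; `1/(breadth_x + breadth_y)` is available by
  configuration since the breadth-weighting rule is not uniquely determined
  by its verbal description. Rates and sizes are correlated on the log
  scale (breadths taken as CI log-ratios); probabilities and growth rates
  (which can be negative) stay on the natural scale. P-values are
  weight-preserving permutations: `y` travels with its own breadth.
  Correlations are only tested within species with `n >= 5` strains; smaller
  species are reported as not tested. Point estimates feed all comparative
  statistics; estimation uncertainty enters only through the weights.

## The synthetic-data module

`build_panel()` generates seeded, replicate-level datasets for a panel of
strains with known ground truth, so every stage of the pipeline is testable
without external data. What it emulates:

* exponential adsorption kinetics with a non-attaching plateau;
* Poisson multiplicity statistics for depolarization
  (binomial cell counts, 300 cells scored per replicate);
* normally distributed lysis times (truncated at 0) and progeny bookkeeping
  through the one-step curve;
* biphasic decay with a persistent fraction;
* plaque-count noise as Poisson counting error behind an idealized serial
  dilution that brings the expected plate count to `target_count`
  (default 200, giving ~7% relative error at every titer — the counting
  regime of a well-run plaque assay);
* lognormal titer error (CV 0.15) on growth-assay measurements;
* a species/type-host grouping scheme (default three groups sized
  {12, 12, 10} on the default 34-strain panel) with genome sizes drawn
  uniformly on 290–370 kb, so variance partitioning and within-species
  tests are exercisable. Species and host are deliberately confounded, as
  in real collections where each species is assayed in its type host.

Default trait ranges span the between-strain spreads such panels show:
burst size per release 10–770 (77-fold), adsorption constant
`5e-8`–`1e-6` mL/h, lysis times 5–12 h, slow mortality
(0.01–0.08 h⁻¹) with a 1–10% persistent fraction; probabilities cover most
of the unit interval. Rates and sizes are drawn log-uniformly,
probabilities and times uniformly. Growth assays are simulated at the
growth rate predicted from the strain's own true traits, which closes the
loop for end-to-end recovery tests.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: replicate-level random effects (plate,
day, culture batch), host physiological state, titer drift between assay
and growth measurement, non-normal lysis-time shapes (e.g. bimodal bursts),
density-dependent adsorption, detection limits and censoring, and real
phylogenetic structure in the trait values (synthetic traits are drawn
independently of the group labels, so the variance-partitioning null holds
by construction).

## Problem sizes used by the test suite

The suite exercises: noise-free recovery on 20 random trait sets (tolerance
1% relative); bias and CI coverage on 200 simulated strains at
`n_boot = 200` (median |relative bias| < 10%, coverage within [88%, 99%]);
solver agreement with a dense-grid root scan on 100 random parameter sets
(1e-6); AIC equivalence against brute-force enumeration on 50 random
datasets; permutation-null uniformity over 200 replicates at
`n_perm = 199`; and a 34-strain end-to-end synthetic study plus a 21-strain
scenario in which trait variation is dominated by specific infectivity.
These sizes were chosen to make the Monte Carlo assertions stable at the
stated tolerances while keeping the default run lightweight.

## Known limitations

* The CI construction is percentile bootstrap; BCa or basic intervals may
  behave better for strongly skewed estimators, and all bootstrap claims
  inherit the independence assumptions above.
* `a` is identified only if the adsorption grid reaches the plateau; with
  slow adsorption (`kH` well below `1/t_max`) `a` and `k` trade off and the
  poorly-resolved flag is the intended outcome.
* The persistent fraction is identified only if the decay series runs long
  enough that `exp(-m t)` falls below `p`; the default grid (25 days)
  matches the default trait ranges, not every conceivable strain.
* The growth prediction treats host density as constant and ignores
  mortality, lysis-time spread, lysogeny and co-infection by design.
* `estimate_burst_sizes()` supports a directly measured `b_d` via its
  plateau-window arithmetic, and `b_r = b_d / r` is a definitional
  consistency rather than an independent measurement; if both are measured
  independently the identity `b_d = r * b_r` becomes a checkable prediction.
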