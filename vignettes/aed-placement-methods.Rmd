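---
title: "Modelling OHCA risk and planning AED placement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling OHCA risk and planning AED placement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedaccess)
```

This vignette explains the models behind `aedaccess`, the choices that were
genuinely open when designing it, and what the synthetic-data experiments do
and do not demonstrate.

## The problem

Out-of-hospital cardiac arrest (OHCA) survival falls steeply with every
minute to defibrillation, so public AEDs only help when one sits within a
one-to-two-minute run — roughly 100 m — of the arrest. Two strands of
methodology address where AEDs should go. *Accessibility scoring* (floating
catchment methods) compares the supply of AEDs with a model-based demand
surface and flags underserved areas, but names no concrete sites.
*Covering optimisation* picks concrete sites maximising how many historical
events fall within the coverage radius, but ignores the spatial risk factors
that drive where future events will occur. `aedaccess` implements both and a
reconciliation between them: a priority ranking of low-access, high-demand
grid cells, against which a proposed placement can be audited.

## Grid and covariates

Events, AEDs and candidate buildings are points; census covariates exist per
municipality. Both are brought to a common 0.01° × 0.01° lattice (about
1.1 km at mid-European latitudes). Each cell belongs to the municipality
containing its centroid, and each municipality covariate is divided equally
among its cells, so the per-covariate sum over a municipality's cells equals
the municipality value. This equal-split is admittedly crude — it assumes
covariates are uniform within a municipality — but it conserves totals and is
the natural choice when no finer data exist.

Two conventions the data formats leave open are fixed here for determinism:
cell boundaries are half-open, `[x, x + size)` in both axes, so every point
belongs to exactly one cell (events on a shared edge count once); and
adjacency is rook (4-neighbour) by default, with queen (8-neighbour)
available by flag — lattice CAR models conventionally use rook contiguity.
Cells whose centroid falls outside every municipality carry no covariates
and are excluded from the model and the rankings.

## The count model

Cell counts `y_i` follow a zero-inflated Poisson ("type 1"): a structural
zero with probability `p`, otherwise `Poisson(lambda_i)` (which can itself
produce zeros),

```
y_i ~ p * delta_0 + (1 - p) * Poisson(lambda_i)
log(lambda_i) = beta0 + x_i' beta + u_i + v_i
p = plogis(theta),  theta ~ N(0.000001, variance 2)
```

with a BYM-type spatial structure: `u` an intrinsic CAR (ICAR) field —
each `u_i` conditionally normal about the mean of its neighbours with
precision `tau_u * n_i`, equivalently the improper joint density
`exp(-tau_u/2 * sum over neighbour pairs (u_i - u_j)^2)` — and `v` iid
`N(0, sigma_v^2)` noise. The `theta` prior makes the zero-inflation
probability a priori mean 0.5 with central 95% mass on roughly (0.06, 0.94):
weakly informative and symmetric. We read the prior's second argument as a
*variance* of 2; of the variance/sd/precision readings it is the one whose
implied percentiles match the (0.05, 0.95) usually quoted for this prior.

Remaining priors are unstated in the sources this model follows and are set
to common lattice-model defaults, all exposed in `zip_car_prior()`:
independent `N(0, 10^2)` on the intercept and coefficients (on the
standardised covariate scale), `Gamma(1, 5e-4)` on `tau_u` and on
`tau_v = 1/sigma_v^2`.

### Inference

The posterior is sampled by Markov chain Monte Carlo
(data augmentation for the structural zeros, adaptive random-walk Metropolis
for `theta` and the regression block, chromatic single-site updates for the
ICAR field, conjugate Gamma updates for the precisions), with the inner loop
in C++. Covariates are standardised internally; reported coefficients are
back-transformed. Identification follows the standard ICAR treatment: `u` is
re-centred to sum to zero each iteration with the mean absorbed into the
intercept.

Two additional move families are not optional extras but what makes the
sampler usable on this model:

* **Deconfounding swaps.** Because covariates are constant within
  municipalities they are spatially smooth, and the ICAR field can absorb
  almost any coefficient shift: `(beta_m, u)` has a likelihood-flat ridge.
  A swap proposes `beta_m -> beta_m + d` together with `u -> u - d * x_m`
  (and likewise against `v`), leaving every `lambda_i` untouched, so
  acceptance depends only on the priors. These moves traverse the ridge in
  O(n) per proposal.
* **Field rescaling.** `u -> c u` (and `v -> c v`) with a log-normal factor
  and the matching Jacobian. Without them the collapsed-field state
  (`u ≈ 0`, `tau_u` enormous) is nearly absorbing: single-site updates
  escape it astronomically slowly, and a single-chain split R-hat can sit at
  1.00 while the chain is stuck there.

Convergence is reported as split-half R-hat on `beta0`, each `beta_m`,
`theta`, `log tau_u` and `log sigma_v`; `converged` requires all below 1.05,
and a failed fit is flagged, never silently accepted.

### Predicted demand

The per-cell predicted count is the posterior mean of the *mixture* mean
`(1 - p) * lambda_i` (flag `demand = "lambda_mean"` switches to the Poisson
component's mean). The mixture mean is the model's actual expectation for
the observed count, which is what a demand surface should be; the
alternative answers "how many events if the cell is not structurally zero".
Residuals are `y_i` minus this predicted count, and their spatial
autocorrelation is tested with Moran's I under binary contiguity weights,
with a one-sided (clustering) permutation p-value.

## Accessibility (two-step floating catchment)

Step 1 gives each AED `j` a supply-to-demand ratio
`R_j = S_j / sum_k D_k G(d_kj, d0)`, the sum over demand points within the
catchment radius `d0` (default 100 m), each weighted by the truncated
Gaussian kernel

```
G(d, d0) = (exp(-(d/d0)^2 / 2) - exp(-1/2)) / (1 - exp(-1/2)),  d <= d0
```

which is 1 at the AED, strictly decreasing, and reaches 0 continuously at
`d0`. A stepwise (piecewise-constant) kernel is available as a sensitivity
variant; its default is a single step of weight 1, because no specific
breakpoints are canonical. Step 2 sums the ratios of the AEDs located inside
each cell: `A_i = sum_{j in cell i} R_j`.

Design choices worth knowing:

* **Demand points are cell centroids** carrying the model's predicted
  counts. With `d0 = 100` m far below the 1.1 km cell size, an AED "sees"
  at most the demand of the one or two centroids it happens to sit near;
  many AEDs have *no* centroid in the catchment at all. Such zero-demand
  AEDs get `R_j = 0` and a flag (rather than an infinite ratio that would
  dominate every ranking); the flagged list is returned for audit. This
  mismatch of scales is inherent to combining a ~1 km demand grid with a
  100 m catchment and is the main caveat on the access scores.
* Distances are great-circle (haversine, sphere radius 6,371 km); no road
  network is used.
* By default every AED counts as supply `S_j = 1`; a flag restricts supply
  to AEDs marked available around the clock.

Total access is conserved: the sum of `A_i` over cells equals the sum of
`R_j` over in-grid AEDs, which the tests check to 1e-10 relative.

## Optimal placement (maximal covering)

Given the historical events not already within the coverage radius
(default 100 m) of an existing AED, choose `N` (default 100) of the candidate
buildings to maximise the number of events covered:

```
max sum_j x_j   s.t.  sum_i y_i = N,   x_j <= sum_i a_ji y_i,   x, y binary
```

with `a_ji = 1` iff event `j` lies within the radius of site `i` (closed
boundary: exactly-at-the-radius counts, with a micron of slack for floating
point). Coverage here is deliberately binary — an event at 99 m counts
fully, at 101 m not at all — unlike the access kernel, which decays smoothly
to 0 *at* `d0`; the two conventions are both stated contracts.

`solve_mclp()` is an exact branch and bound over distinct coverage columns
with the submodular bound (current coverage plus the largest remaining
marginal gains), seeded by the greedy solution. Among equal-objective optima
it returns the lexicographically smallest selected-site set, found by a
reconstruction pass, so results are reproducible across platforms — integer
programs otherwise return an arbitrary optimum. Duplicate candidate
coordinates are collapsed to the lowest site id first. On instances too
large for the node budget the greedy solution is returned with
`optimal = FALSE`; greedy's classic `1 - 1/e` guarantee and its agreement
with the exact solver on every small random instance are both under test.

## Priority ranking and evaluation

Cells with predicted count above a threshold (default 1) are ranked by
lowest access, ties by highest predicted count, final ties by cell id — a
total, deterministic order. The evaluation joins the placement solution to
this ranking: one table lists the top-20 priority cells with the number of
new AEDs each received; the other lists the top-20 cells by AEDs received
(ties resolved by better priority rank) with their ranks. Reading the two
tables together shows whether an event-coverage optimiser serves the
low-access areas or concentrates on high-count cells.

## Synthetic data: what it emulates, what it does not

`simulate_study()` generates the full study at desk scale: a 20 × 20 lattice
(400 cells) partitioned into 40 contiguous municipalities by seeded region
growing (one random seed cell each, then random frontier expansion — always
a partition, always reproducible); municipality covariates from Beta
(proportions), Dirichlet-split settlement hectares (land uses), and
log-normal (population density, financial strength) distributions; counts
from exactly the ZIP + ICAR model above; events uniform within their cell;
AEDs (90) and candidate buildings (1,500) uniform over the region. The ICAR
field is drawn exactly by eigendecomposition of the structure matrix with
the null eigenvector dropped.

Default generative values (all overridable in `generative_params()`) were
chosen once to reproduce the count *marginals* of a cantonal OHCA registry
at this scale — about 80% zero cells, a mean count below one, occasional
urban cells with counts in the tens driven by the population-density tail —
with moderate covariate effects (each contributing ~0.1–0.4 sd on the log
scale) and a spatial field (`tau_u = 8`, marginal sd ≈ 0.3) comparable to
the unstructured noise (`sigma_v = 0.2`).

What passing tests on these data do **not** show: anything about road-network
travel, within-municipality covariate heterogeneity, non-uniform AED or
building siting (real AEDs cluster where people are), or the actual
covariate–risk relationships of any region. The generator shares the
model's own assumptions, so model-fit checks on it are consistency checks,
not external validation.

### The calibration study

The interval-calibration experiment (50 replicates, 400 cells) deliberately
uses a more informative configuration than the sparse defaults:
`beta0 = 0.7`, `p = 0.3`, and three well-separated covariates (proportion
male, proportion over 65, financial strength). The reason is statistical,
not cosmetic: frequentist coverage of Bayesian intervals at a *fixed* truth
is only guaranteed asymptotically, where the likelihood dominates. Under the
sparse marginals (≈80% zeros, mean ≈0.8) the random-effect scales are weakly
identified; the posterior then legitimately concentrates on a collapsed
field, coefficients of spatially smooth covariates absorb part of the field,
and intervals undercover slightly — a property of the inference problem that
a longer chain does not change (verified against long reference runs). The
calibration study therefore checks the sampler where calibration is
meaningful, while the pipeline defaults keep the realistic sparse regime.
Chains use 40,000 iterations (15,000 burn-in); at 400 cells one fit takes a
few seconds, the 50-replicate study a few minutes.

## Numerical choices and degenerate inputs

* Seeds are explicit arguments everywhere randomness exists (generator,
  sampler, permutation test); identical seeds give bit-identical outputs,
  including the pipeline's files.
* Constant (zero-variance) covariates are an error, not a silent drop.
* Constant residuals make Moran's I undefined and raise an error.
* An AED with zero decayed demand gets ratio 0 plus a flag (see above).
* Disconnected adjacency graphs are refused with the component count, both
  when sampling the ICAR field and when fitting.
* `p = 1` with a positive count correctly yields a log-likelihood of
  `-Inf`.
* The half-open cell rule decides all boundary ties; the coverage matrix
  uses a closed radius with 1e-6 m slack.

## Known limitations

* Straight-line distances throughout; road-network distances would change
  both access scores and coverage in mountainous regions.
* The demand-at-centroids convention under a 100 m catchment (above).
* Single global zero-inflation probability `p`, as in the model this
  implements; spatially varying zero-inflation is out of scope.
* The exact solver's node budget: at the full case-study scale
  (N = 100 over ~10^5 buildings) expect the greedy fallback, flagged
  `optimal = FALSE`, rather than a proven optimum.
* Municipality polygons produced by the generator are unions of cell
  squares (with internal seams), sufficient for centroid assignment but not
  cartographic output.
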