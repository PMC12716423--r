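---
title: "Modeling the assembly of alpine floras: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the assembly of alpine floras: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpassembly)
```

## The scientific problem

Regional alpine floras accumulate species through a small set of
macroevolutionary routes: **in situ speciation** (an alpine lineage splits
within its region), **subset speciation** (a regional alpine endemic buds off
from an ancestor with a wider range and/or occupancy of both the alpine and
nonalpine biome), **colonization** (an alpine lineage disperses into a new
region), and **niche expansion** or local recruitment (a resident nonalpine
lineage evolves into the alpine biome). `alpassembly` provides the machinery
to model these processes jointly on time-calibrated phylogenies, to sample
replicate evolutionary histories consistent with tip data, to turn those
histories into per-capita rate series and assembly summaries, and to relate
interchange between regions to the physical connectivity of cold habitats
through time.

## The compound-state model

A lineage's state couples a **geographic range** — a nonempty set of regions
constrained to induce a connected subgraph of a user-supplied adjacency
matrix, with at most `max_range_size` members — with a **biome flag**:
`NONALPINE`, `ALPINE`, or `BOTH`. Biome occupancy is uniform across the
range: a biome shift applies to all occupied regions at once. Anagenetic
moves change exactly one component: gain of one adjacent region (rate
`dispersal` x number of occupied neighbors of the gained region), loss of one
region (rate `extirpation`, provided the remainder stays connected), or a
biome shift between a pure state and `BOTH` (rate `biome_rate`). A direct
`ALPINE <-> NONALPINE` jump is impossible; the shift must pass through
`BOTH`, which makes `BOTH` the gateway state for local recruitment.

Cladogenesis is state dependent (the ClaSSE family). A within-region event in
region `r` keeps one daughter in the parent state and makes the other an
endemic of `r`; from a single-biome parent the endemic inherits that biome,
while a `BOTH` parent may produce an endemic in any of the three biome
states — this is the only reading under which subset speciation (alpine
endemics budding off widespread `BOTH` ancestors) can occur, and we adopt it.
The regional rate `lambda_within[r]` is split equally among region `r`'s
distinct outcomes so that the total speciation propensity of a state is
parameterization independent. Between-region (vicariant) events split the
range into two connected halves, both inheriting the parent biome, with
`lambda_between` divided equally among the valid bipartitions. Lineage death
is modeled only for endemic states (`mu[r] = extirpation[r]`): for a
widespread lineage, local extinction is a range contraction, not death.

With the default six-region configuration shipped in
`northern_hemisphere_regions()` the space has 111 states at
`max_range_size = 4`; the counts are sensitive to the adjacency matrix and
the range cap, both of which are fully exposed, because no single printed
configuration pins them down.

### Likelihood

The likelihood integrates the standard coupled system for extinction
probabilities `E_i(t)` and partial likelihoods `D_i(t)` tip-to-root along
every branch, combining daughters through the cladogenetic tensor at nodes.
Incomplete sampling enters through `D(0) = rho` on compatible tip states and
`E(0) = 1 - rho`, which is what lets the model account for unobserved
speciation and extinction. The integrator is an adaptive Cash-Karp
Runge-Kutta scheme in C++ (relative tolerance `1e-8`, absolute `1e-10`) with
per-branch log-rescaling of `D` so that partial likelihoods never underflow
on large trees. `E` is clamped to `[0, 1]` against roundoff after each
accepted step.

Three decisions are deliberately exposed because the underlying literature
varies and no single convention is canonical:

* **Root treatment** — likelihood-proportional (FitzJohn-style) state weights
  by default; `flat` and `fixed` weights are options.
* **Conditioning** — on the root lineage speciating with both daughter clades
  surviving, on by default, with a toggle (the closed-form checks in the test
  suite run unconditioned).
* **Extirpation sharing** — a scalar `extirpation` is shared across regions
  by default; a vector gives per-region rates.

A dispersal rate is included even though range expansion is sometimes left
implicit in verbal model descriptions: colonization events cannot be inferred
without a rate for them, so the parameter is structurally required.

### Stochastic mapping

Replicate joint histories are drawn conditional on the data: node states
root-to-tip from their exact joint conditional distribution (using the stored
per-branch partials), then each branch is filled by rejection sampling of the
anagenetic process augmented with **hidden speciations** — a cladogenetic
event whose second daughter leaves no sampled descendants, entering at rate
`lambda_{i,jk} E_k(t)`. The time dependence of `E` is handled by linear
interpolation on a fixed grid (100 points per Ma by default) and exact
thinning against the constant bound `q_total + 2 lambda_total + mu`; a death
candidate rejects the whole branch attempt, which implements the survival
conditioning of observed branches without any approximation beyond the `E`
grid. A branch whose endpoint is missed repeatedly errors out at an
acceptance floor of `1e-4` (10,000 attempts) with advice to revisit the
parameters, rather than silently looping. Each replicate `m` is drawn under
`seed + m`, so any single map can be regenerated without redrawing the rest.

## Event accounting

`classify_events()` re-derives biological events from a history's raw state
changes; the simulator keeps its own tally as it generates truth histories,
and the test suite requires the two independent code paths to agree exactly.
A cladogenetic event is counted in region `r` when it creates a *new*
alpine-occupying lineage there (the alpine-lineage count increases by one):
it is in situ speciation when the parent is exactly the alpine endemic of
`r`, and subset speciation when the parent's state strictly contains `r`'s
alpine occupancy — wider range, `BOTH` biome, or both, distinguished in a
`detail` column. We count a daughter in state (`r`, `BOTH`) as a subset
event too: it is a new regional lineage occupying the alpine biome, and
excluding it would break the exact bookkeeping identity below. Colonization
is attributed to the source regions occupied at the event time with equal
weights summing to one (an adjacent-only attribution is available); niche
expansion and contraction are counted once per occupied region, because the
per-region lineage ledger is what downstream rates divide by.

The per-region **lineage count** `n` is the running balance of in situ +
subset speciation + niche expansion + colonization − local extinction −
niche contraction. The contraction term is included (although narrations of
the balance often omit it) because without it the balance would drift above
the census whenever a `BOTH` lineage returns to nonalpine; with it, the
balance at the present equals the census of extant alpine lineages exactly,
and the test suite asserts this identity on simulated truth. The balance
starts at the root: a root lineage that already occupies the alpine biome in
a region contributes `initial = 1` there, since no event created it.

**Bins and rates.** Count bins are half-open 1-Ma age intervals `(t-1, t]`
labeled by their older edge; an event at exactly an integer age belongs to
the younger bin. The per-capita rate of bin `t` is `s(t) / n(t)` with `n`
evaluated at the bin's older edge — the count standing at the end of the
previous period. Bins with a zero lagged count get rate 0 rather than `NaN`,
matching the masking intent of suppressing pre-origin noise; wherever the
lagged count is positive, `rate x count` returns the integer event count
exactly. Replicate ensembles are summarized by binwise medians and 25/75%
quantiles (linear-interpolation type-7 quantiles — stated because replicate
counts are small in tests), and `mask_leading()` zeroes each quantile
trajectory before its last zero, independently per trajectory.

## Habitat connectivity

Per time step, pixels whose annual mean temperature rounds (half away from
zero) into the closed window `[0, 6]` degC form the alpine biome; connected
components under the 8-neighborhood (4 available) are habitat patches.
Movement resistance is the rounded temperature's distance from the window —
zero on alpine pixels, `max(0, T-6, -T)` elsewhere, impassable on nodata.
Between adjacent pixels the step cost is the mean of their resistances times
the step length (1 orthogonal, `sqrt(2)` diagonal, in cell units): a
symmetric, additive rule that is exactly zero inside patches. Patch-to-patch
least-cost distances are multi-source Dijkstra runs over this lattice; links
with cost strictly below 250 are retained (no planar pruning — a link exists
whenever the threshold holds). Movement probability decays as
`exp(-k cost)` with `k = log(20)/150`, i.e. exactly 0.05 at cost 150. The
**probability of connectivity** is

`PC = sum_ij a_i a_j p*_ij / A^2`

over ordered patch pairs including `i = j` (`p*_ii = 1`), with `p*_ij` the
maximum path product over retained links and `A` the total alpine area — so
PC is the probability that two random alpine pixels are interconnected, and
a single patch scores exactly 1. The classical variant that divides by a
fixed landscape area is available through `total_area`, since the older
connectivity literature normalizes that way. Ice sheets, coastlines and
sea-level barriers are deliberately ignored: at million-year steps the
temperature field is the only resistance worth modeling.

Grids are consumed as plain equal-area matrices (ESRI ASCII grid IO is
provided); reprojection of longitude/latitude products to an equal-area grid
is treated as a preprocessing contract of the caller, and no projection code
is hard-wired.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage can be exercised without any downloads.

* `make_paleo_grids()` builds temperature fields as a latitudinal gradient
  plus conical massifs under a fixed lapse rate, a per-step global offset
  (monotone decreasing offsets emulate long-term cooling), and a seeded
  smooth noise field (a truncated sum of random cosine modes, default
  amplitude 0.5 degC, correlation length 5 cells). The noise is drawn once
  per scenario — it is topographic texture, not weather — so with zero noise
  alpine area grows exactly monotonically under monotone cooling.
* `clade_scenario()` presets pin contrasting assembly regimes.
  `SPECIATION_ENGINE` concentrates within-region speciation in the focal
  region (0.45 vs 0.08/lineage/Ma elsewhere). `RECRUITMENT` starts the root
  nonalpine with a high biome-transition rate (0.35). `CROSSROADS` models a
  region assembled by immigration: a species-rich source region (0.45-scale
  diversification is not needed; 0.25 suffices), a focal region with little
  in-place speciation (0.05), high dispersal (0.4) and high turnover
  (extirpation 0.15) so lineages repeatedly drop out of the focal region and
  recolonize — without the turnover, widespread ranges convert would-be
  colonization dominance into subset speciation, which is the mechanistic
  reason the preset carries a high extirpation rate. Simulated clade sizes
  in the tests are kept at hundreds of tips (crown ages 15-18 Ma), which
  keeps the full suite comfortably fast while leaving hundreds of events per
  replicate.
* `make_occurrences()` draws per-species records around local treelines with
  known alpine fractions; `classify_by_treeline()` flags records at or above
  the treeline as alpine (the treeline is the *lower* boundary of the alpine
  biome, so ties count alpine), and `classify_species_biome()` applies the
  25%/5% occurrence-fraction thresholds, inclusive at the stated minima
  ("minimum percentage required").

What passing tests on these generators shows is internal consistency and
statistical calibration of the machinery — likelihoods against independent
integrators, mapping frequencies against exact conditionals, estimators
against generating rates, connectivity against enumeration oracles. What
they cannot show is anything about real floras: empirical occurrence data
are spatially biased, real paleoclimate fields have structure no cosine
field reproduces, and real clades violate constant-rate assumptions. The
synthetic scenarios are calibration instruments, not mimics.

## Numerical choices and degenerate inputs

* ODE tolerances `rtol 1e-8` / `atol 1e-10` (the ML fitter loosens to
  `1e-7`/`1e-9` for speed inside the optimizer); per-branch log-rescaling.
* Rejection-sampling floor `1e-4` per branch; thinning bound
  `q_total + 2 lambda_total + mu`.
* The quantile definition, the bin convention and the treeline/threshold tie
  rules are stated above and asserted in tests; `mask_leading` is idempotent
  by construction.
* Degenerate inputs error early and loudly: empty region sets, non-symmetric
  adjacency, non-binary or unrooted trees, tips without data, all-nodata
  grids, zero alpine area, negative costs, broken state chaining in
  histories (errors name the branch and event).
* Total extinction of a simulated clade signals a condition of class
  `alpassembly_extinct` rather than returning silently; runaway growth is
  guarded by `max_lineages`.

## Known limitations

* ML fitting is intended for parameter-recovery studies; no Bayesian
  sampler is provided, and no attempt is made at the throughput of dedicated
  SSE engines on state spaces with hundreds of states.
* Stochastic mapping requires the rejection sampler to hit branch endpoints;
  under extreme rate regimes the acceptance floor will trigger. This is a
  property of rejection-style mapping generally.
* The connectivity module assumes equal-area grids and ignores physical
  barriers by design.
* Histories produced by other software can be read as long as they conform
  to the JSON schema; the native string format of other mapping tools is not
  parsed.
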