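# alpassembly

Tools for studying how regional alpine floras were assembled, and how
climate-driven habitat connectivity shaped floristic interchange among
mountain systems.

Alpine species accumulate in a region through a handful of macroevolutionary
routes: **in situ speciation** (an alpine lineage splits within its region),
**subset speciation** (a regional alpine endemic buds off an ancestor with a
wider range and/or occupancy of both biomes), **colonization** (an alpine
lineage disperses in from another region), and **niche expansion** (a
resident nonalpine lineage is recruited across the treeline). `alpassembly`
implements the full quantitative chain needed to estimate the contributions
of these processes from time-calibrated phylogenies, and to relate
between-region interchange to the physical connectivity of cold habitats
over millions of years.

## What is inside

* **Compound-state diversification model (ClaSSE family).** A lineage's
  state pairs a geographic range (an adjacency-constrained region set) with
  a biome flag (`NONALPINE`, `ALPINE`, `BOTH`). Exact likelihoods solve the
  coupled extinction/likelihood ODE system

  `dE_i/dt = mu_i - (Lambda_i + Q_i + mu_i) E_i + sum_j Q_ij E_j + sum_jk lambda_ijk E_j E_k`

  `dD_i/dt = - (Lambda_i + Q_i + mu_i) D_i + sum_j Q_ij D_j + sum_jk lambda_ijk (D_j E_k + D_k E_j)`

  with a compiled adaptive Runge-Kutta core, accounting for extinction and
  incomplete sampling (`rho`). Forward simulation and rejection-style
  stochastic mapping (with hidden speciation events at rate
  `lambda_ijk E_k(t)`) produce replicate joint histories.
* **Event format and accounting.** Histories serialize to a versioned,
  extensible JSON schema (branches with start/end states and ages plus
  typed, timed events). `classify_events()` turns raw state changes into
  assembly processes; binned per-capita rates follow
  `lambda(t) = s(t) / n(t-1)` with a per-region lineage ledger, 25-75%
  quantile envelopes, leading-zero masking, interchange matrices and
  assembly-proportion summaries.
* **Habitat connectivity.** From gridded annual-mean temperature: alpine
  pixels are those whose rounded temperature lies in [0, 6] degC; patches,
  temperature-deviation resistance surfaces, least-cost paths (links kept
  below cost 250), movement probability `exp(-k d)` calibrated to 0.05 at
  cost 150, and the probability of connectivity
  `PC = sum_ij a_i a_j p*_ij / A^2` per time step.
* **Synthetic data.** Paleo-temperature grid sequences (latitudinal
  gradient, conical massifs, monotone cooling, seeded smooth noise), clade
  scenarios with contrasting generating regimes, and occurrence tables for
  the treeline/threshold biome classifier.

## A worked example

Simulate a "speciation engine" clade (high within-region speciation in the
focal region), classify its true history, and summarize assembly:

```r
library(alpassembly)

sc  <- clade_scenario("SPECIATION_ENGINE", seed = 42)
res <- make_scenario_clade(sc)
res$n_extant
#> [1] 615

ev <- classify_events(res$history, sc$space)
ap <- assembly_proportions(list(ev), "R1")
round(ap$shares, 3)
#>    cladogenesis    colonization niche_expansion
#>           1.000           0.000           0.000
round(ap$cladogenesis_breakdown, 3)
#> in_situ  subset
#>   0.889   0.111
```

In this simulated clade, all alpine assembly in the focal region is
cladogenetic (the generating regime has little dispersal and biome
turnover), and 89% of the cladogenetic events are in situ speciations —
alpine daughters of alpine endemic ancestors — versus 11% subset
speciations. The per-capita rate pipeline on the same events:

```r
rs <- rate_series(list(ev), "R1", initial = 1)   # the root was alpine in R1
tail(rs$envelope, 3)
#>    bin       q25    median       q75
#> 13   3 0.3764045 0.3764045 0.3764045
#> 14   2 0.4218750 0.4218750 0.4218750
#> 15   1 0.4459103 0.4459103 0.4459103
```

The median per-capita in situ speciation rate in the youngest bins runs at
0.38-0.45 events/lineage/Ma, approaching the generating within-region rate
of 0.45 (the envelope is degenerate because a single replicate was
supplied). A connectivity series over a synthetic cooling sequence:

```r
grids <- make_paleo_grids(grid_scenario(
  nrow = 30, ncol = 30, base_temp = 24, noise_amplitude = 0,
  massifs = data.frame(row = 15, col = 15, radius = 8, peak_elevation = 4),
  offsets = c(0, -5, -10), seed = 3))
pc_time_series(grids)
#>   time n_patches alpine_area n_edges        pc
#> 1    2         1      125000       0 1.0000000
#> 2    1         2      502500       1 0.9456617
#> 3    0         1      977500       0 1.0000000
```

Cooling grows the alpine area eightfold; PC dips when the massif ring and
the expanding high-latitude band briefly form two patches, then returns to 1
when they merge.

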