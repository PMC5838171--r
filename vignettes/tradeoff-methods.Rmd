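---
title: "Multi-sector tradeoff analysis for offshore aquaculture siting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sector tradeoff analysis for offshore aquaculture siting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspfrontier)
```

## The planning problem

Offshore aquaculture competes for ocean space with existing uses and
environmental concerns. `mspfrontier` implements a coordinated
marine-spatial-planning (MSP) engine for a domain of discrete planning units
(sites), each of which receives exactly one development option
$p \in \{\mathrm{NONE}, \mathrm{MUSSEL}, \mathrm{FINFISH}, \mathrm{KELP}\}$.
Seven sectors are modelled by default: three aquaculture *gain* sectors
(mussel longlines, finfish pens, kelp longlines), the wild-capture halibut
fishery (a gain sector excluded from developed sites), and three *impact*
sectors — viewshed (person-views of farm structures from shore), benthic
health (organic carbon flux beneath finfish pens), and disease risk
(eigenvector centrality of a farm-to-farm hydrodynamic connectivity matrix).
The sector set is configurable; these seven are the defaults.

## From responses to a common currency

Each sector $n$ has a response $R_{n,i,p}$ to option $p$ at site $i$ in its
native units. Gain sectors take their response as value; impact sectors take
the distance of their response below the sector-wide maximum response
$\bar R_n = \max_{i,p} R_{n,i,p}$, so more impact means less value:

$$V_{n,i,p} = \begin{cases} R_{n,i,p} & n \text{ gain} \\
\bar R_n - R_{n,i,p} & n \text{ impact.} \end{cases}$$

Values are made commensurable by scaling each sector by the domain-wide value
it would attain were its ideal option chosen at every site:

$$X_{n,i,p} = \frac{V_{n,i,p}}{\sum_i \max_p V_{n,i,p}},$$

so $X \in [0,1]$ and $\sum_i \max_p X_{n,i,p} = 1$ exactly. Options that are
not developable at a site — outside the depth window, inside an exclusion
zone, or with negative amortized profit — are masked: they carry the site's
no-development response and can never be chosen. Negative-annuity masking
follows the economic rule that sites whose net present value and annuity are
negative are treated as undevelopable for that farm type.

Discounting uses the printed-form convention $\mathrm{NPV} = \sum_{t=0}^{T}
\pi_t/(1+\delta)^t$ ($T+1$ cash flows for a $T$-year horizon, year 0
undiscounted; `include_t0 = FALSE` switches to the $t = 1..T$ convention),
with defaults $\delta = 0.05$, $T = 10$. The equivalent annual annuity is
$\delta\,\mathrm{NPV}/(1-(1+\delta)^{-T})$, computed via `expm1` so the
$\delta \to 0$ limit $\mathrm{NPV}/T$ is reached without cancellation.

## The frontier

Given sector weights $\alpha_n \in [0,1]$, the per-site objective is
$\mathrm{Obj}_i = \max_p \sum_n \alpha_n X_{n,i,p}$ over the permitted
options. Because the objective is additively separable across sites, the
per-site argmax is an exact global optimum — no heuristic search is
involved. Ties within $10^{-12}$ break to no development, then mussel,
finfish, kelp, for reproducibility and development-conservatism. The all-zero
weight vector is degenerate and returns the no-development plan with a
warning.

`enumerate_frontier()` sweeps the full Cartesian grid of per-sector weights —
six weights $\{0, 0.2, \ldots, 1\}$ over seven sectors gives
$6^7 = 279{,}936$ exact optimal plans. Internally the sweep is chunked
matrix algebra (weights-by-sector times sector-by-site-option blocks), with
all reductions in fixed site order; plans are not stored by default because
any entry's plan re-derives deterministically from its weights
(`frontier_plan()`), while per-site development frequencies are accumulated
during the sweep for `hotspot_map()`. A guard refuses grids beyond
`max_entries` combinations.

Outcomes express a plan's cumulative scaled value per sector as a percentage
of the sector's range between full development (gain sectors at their
maximum; existing sectors maximally impacted) and no development:

$$O_n = 100\,\frac{\sum_i X_{n,i,p_i} - \sum_i \min_p X_{n,i,p} + E_n}
{\sum_i \max_p X_{n,i,p} - \sum_i \min_p X_{n,i,p} + E_n},$$

where $E_n \ge 0$ is value the sector holds outside the planning domain
(`extra_value` in the sector table; zero by default). The external constant
enters the achieved sum and the range, bounding the sector's minimum outcome
at $100E_n/(\text{range} + E_n)$: a fishery holding 13.3 times the in-domain
range outside the domain can never fall below about 93%. The constant is
deliberately *not* added to the minimum term, which would cancel and restore
a 0% floor. Outcomes are mathematically confined to $[0,100]$; summation
noise of order $10^{-11}$ from chunked BLAS reductions is snapped to the
bounds (tolerance $10^{-6}$).

## Conventional planning and the value of MSP

The conventional-planning counterfactual ranks each developable (farm type,
site) pair by a suitability index: the annuity if developed there divided by
the scaled-value loss of the most impacted existing sector. Measuring the
impact on scaled values keeps it commensurable across sectors. Sites with no
measurable impact get infinite suitability and rank among themselves by
annuity, then site order; development that would *benefit* an existing
sector counts as zero impact. The *unconstrained* variant develops sites in
global rank order (a taken site is unavailable to other farm types); the
*constrained* variant rotates, always letting the farm type with the
smallest footprint pick its best remaining site, and continues among the
remaining types once one exhausts its candidates.

`value_of_msp()` projects the 7-D frontier to continuous 2-D efficiency
frontiers and measures, sector by sector, how much better coordinated
planning does than a conventional trajectory at the same development level.
Three methodological choices matter:

* **Level currency.** Development level is the farm type's outcome
  percentage — its share of full development value — the same currency the
  framework uses everywhere ("developed to 25% of its maximum value").
  Site-count (footprint) matching is available as an alternative.
* **Pairwise frontiers.** The 2-D frontier for (farm type $a$, sector $n$)
  is the concave upper boundary of the entries whose weights fall only on
  $a$ and $n$. These entries are the exact scalarization optima of the
  $(a, n)$ bi-objective problem at the grid's weight ratios, so every vertex
  of the interpolated frontier is a global optimum for some supported weight
  direction. An envelope over *all* entries was tried and rejected: entries
  whose footprints arise from unrelated sectors' weights pollute the
  projection, and binned-envelope chords exhibit sub-0.1-point dips below
  feasible greedy trajectories wherever the suitability ranking locally
  coincides with a pair-optimal ordering.
* **Comparison at frontier points.** The difference is evaluated at each
  point of the 2-D frontier, with the conventional trajectory interpolated
  linearly between its site-by-site steps (anchored at the no-development
  baseline). Because an interpolated conventional point is a convex
  combination of feasible outcomes, it is bounded by each vertex's
  supporting hyperplane — so a negative value of MSP at a frontier point
  cannot arise from interpolation error, only from genuine dominance
  failure. Levels the trajectory never reaches are gaps (`NA`), not
  failures: no like-for-like comparison exists there.

Under these choices the dominance of coordinated planning over both
conventional variants holds to floating precision on the shipped fixtures,
and the mean value of MSP is tens of percentage points.

## Planning products

`filter_plans()` keeps frontier entries in which every aquaculture sector
exceeds a minimum outcome while no existing sector is impacted beyond a cap
(both 5% in the canonical exercise; impact is $100 - O_n$). `hotspot_map()`
reports per-site development frequency across plan sets. `bray_curtis()`
measures plan dissimilarity; the default one-hot encoding makes Bray-Curtis
exactly the fraction of sites with differing choices, invariant to how
option codes are assigned, while the literal integer encoding is retained
for comparability. `seed_plans()` deduplicates the plan set, clusters it by
single linkage — applied directly to the Bray-Curtis matrix by default, with
linkage in the 2-D ordination's Euclidean space as an option — embeds it by
non-metric multidimensional scaling (Kruskal stress-1, seeded restarts,
non-convergence is an error reporting the stress), and picks one seed plan
per cluster: the member farthest from the global embedding centroid, so the
seeds span the variation in spatial design. The cluster count defaults to
the largest $k \le 8$ whose clusters all have at least two members.

## The synthetic seascape

`sim_seascape()` generates complete, statistically structured inputs so the
whole engine runs and is testable without external data. Sites sit on a
rectangular 1-km grid with a smooth monotone offshore depth gradient plus
smoothed noise; mussel and kelp longlines are permitted at 20-80 m, finfish
pens at 30-100 m, and randomly placed coherent exclusion zones (emulating
protected areas, shipping lanes, and military zones) remove a configured
fraction of sites from all aquaculture. Value surfaces are
Gaussian-kernel-smoothed lognormal noise around sector-specific hotspots
(Gaussian bumps with configurable centres, radii, and optional blanket base
levels), chosen over variogram simulation for simplicity; aquaculture
sectors carry year-0 capital outlays and level annual operating profits that
are amortized through the package's own economics, so negative-annuity
masking arises naturally away from each sector's economic core. The
viewshed surface combines exponential offshore decay with an alongshore
population profile (Gaussian "cities"), mirroring how person-views
concentrate near population centres. Connectivity is a distance-decay
kernel with a directional advection offset and a sparsity threshold. All
randomness flows from one seed through R's default Mersenne-Twister
generator, and the generator restores the caller's RNG state.

The preset conditions were fixed at design time to exhibit the regimes the
framework is meant to probe, and are not tuned thereafter:

* `tiny` (5 sites) — small enough for exhaustive $4^S$ whole-domain
  enumeration, the oracle for the separability property.
* `conflict` (15 x 15) — the fishery hotspot sits on the mussel grounds over
  a blanket fishery base, forcing a strict, strictly-decreasing
  mussel-fishery tradeoff.
* `segregated` (15 x 15) — disjoint, economically tight sector hotspots;
  with no spatial overlap there is no tradeoff, and all three aquaculture
  sectors exceed 95% of their value simultaneously at full weights.
* `scb-like` (33 x 33, 1089 sites) — a bight-scale domain with broad
  aquaculture surfaces (most of each depth window is developable, with
  mild value concentration), near-uniform benthic flux, city-structured
  viewshed, advective disease connectivity, and a fishery holding 13.3
  times its in-domain value outside the domain (floor about 95%). Under
  the 5%-value / 5%-impact policy this seascape yields a small nonempty
  filtered plan set, qualitatively mirroring the canonical filtering
  exercise.

What the generator does *not* emulate: real bathymetry or geography, dollar
magnitudes, within-site farm-scale dynamics, or oceanographic particle
tracking — connectivity is a kernel, not a circulation model. Passing tests
therefore demonstrate the engine's mathematical properties (exact
optimality, scaling identities, dominance, reproducibility) on structurally
realistic inputs, not predictions for any real seascape.

## Numerical choices and limitations

* Tie tolerance $10^{-12}$ absolute in the argmax; fixed site-order
  reductions for bitwise reproducibility; chunk size 2048 weight vectors.
* Eigenvector centrality by power iteration (tolerance $10^{-10}$, at most
  10,000 iterations) on $C + cI$ with $c$ half the largest row sum — the
  shift leaves eigenvectors unchanged but guarantees a strictly dominant
  eigenvalue, so bipartite connectivity graphs converge. Unit-sum
  normalization; row-standardization is exposed as an option since the
  directionality convention is not canonical.
* Problem sizes in the test suite: full $6^7$ enumerations on the 1089-site
  and 225-site fixtures; exhaustive-search oracles on 100 random domains of
  3-6 sites with 100 random weight vectors each; correlogram checks on
  25 x 25 grids averaged over 20 replicates.
* The frontier is exact for the weight grid supplied, but the grid is a
  finite sample of preference space: outcomes between grid ratios are
  reachable only as interpolations, which is why the value-of-MSP
  comparison is anchored at frontier points.
* A weight of zero on every sector, sectors with no domain-wide value, and
  all-zero connectivity matrices are rejected or flagged rather than
  silently accepted.

## A worked run

```{r, eval = FALSE}
library(mspfrontier)

sea <- make_fixture("conflict", seed = 1)
scaled <- scale_values(build_values(sea$responses))
frontier <- enumerate_frontier(scaled)          # 279,936 exact optima
traj <- conventional_plan(scaled, "unconstrained")
vom <- value_of_msp(frontier, traj)
filter_plans(frontier, min_aqua = 2, max_impact = 60)
autoplot(frontier, "mussel", "halibut")
```
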