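---
title: "Measuring spatial accessibility to emergency services with catchfca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial accessibility to emergency services with catchfca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchfca)
```

## The problem

Emergency health care is delivered from fixed sites to a dispersed
population, so geography is itself a barrier to access. Closing or
consolidating emergency services — as health-system reforms periodically do
— changes how long people must travel and how many physicians effectively
serve each community. `catchfca` measures this *potential spatial
accessibility* on a road network and quantifies what a facility-closure
reform changes: who falls outside a tolerable isochrone, how mean travel
times move, and how standardized accessibility scores shift by region.

## The accessibility model

The core index is the **enhanced two-step floating catchment area
(E2SFCA)**, a gravity-type measure computed in two passes over a
travel-time matrix $d_{ij}$ between population centroids ("demand points")
and facilities.

**Step 1** assigns each facility $j$ a supply-to-population ratio over its
catchment:

$$R_j = \frac{S_j}{\sum_{k:\, d_{kj} \le C} P_k \, W(d_{kj})}$$

where $S_j$ is the facility's physician count, $P_k$ the population of
demand point $k$, and $C$ the catchment size (30 minutes by default).

**Step 2** sums, for each demand point $i$, the decay-weighted ratios of
all facilities it can reach:

$$A_i = \sum_{j:\, d_{ij} \le C} R_j \, W(d_{ij})$$

$A_i$ has units of physicians per person. Because both steps use the same
travel-time matrix and the same weights, the construction conserves
supply exactly:

$$\sum_i P_i A_i = \sum_j S_j$$

over facilities whose weighted catchment population is positive. The test
suite asserts this identity to $10^{-9}$ relative error on every instance
it generates, and it doubles as the pipeline's built-in sanity check
(logged on every run).

### The stepped distance-decay

$W(\cdot)$ is a stepped decay over three travel-time zones splitting the
catchment into equal thirds:

| zone | interval (min) | weight |
|------|----------------|--------|
| 1    | $(0, C/3] = (0,10]$   | 1    |
| 2    | $(C/3, 2C/3] = (10,20]$ | 0.42 |
| 3    | $(2C/3, C] = (20,30]$  | 0.03 |

The weights are a stepped discretisation of a Gaussian decay with
parameter $\beta = 1.15$; `decay_scheme()` stores $\beta$ as provenance
metadata only and treats the weight vector as the operative constants, so
alternative weight vectors (or a different $C$, which rescales the
breakpoints) can be supplied without touching the code. Three numerical
conventions matter:

* zone boundaries are **right-closed**: $t = 10$ is zone 1, $t = 20$ zone 2;
* $t = 0$ (demand co-located with a facility) is assigned to zone 1, so
  co-location never loses access even though the zone intervals are
  formally open at 0;
* times beyond $C$ get weight 0: the pair simply drops out of both steps.

A facility whose weighted catchment population is zero gets $R_j = 0$ with
a warning rather than an error; such facilities are excluded from the
conservation identity.

### Standardization

Raw indices are rescaled to $[0,1]$ by a single global min–max transform,
$Z_i = (A_i - A_{\min})/(A_{\max} - A_{\min})$, across all demand units of
a run (not per region). If all values coincide the transform is undefined
and every score is set to 0 with a warning.

Min–max standardization has a real limitation worth understanding when
comparing scenarios: the normalizer is the single best-served demand unit.
If a reform touches the catchment of *that* unit, $A_{\max}$ falls and
standardized scores elsewhere can rise even though every raw score is
non-increasing (raw scores are provably monotone under facility removal —
deactivating a facility never raises any $A_i$, because step-1 ratios of
the remaining facilities are unaffected). Regional comparisons of
standardized means are therefore meaningful when the maximum sits in a
dense metropolitan core far from the closures, which is the situation the
synthetic generator's defaults reproduce. Raw-index deltas are always
directionally safe.

## Travel times

Road segments are traversed at class-specific speeds (motorway 110,
primary 80, secondary 60, local 40 km/h — a single "ambulance = car"
travel mode; congestion, turn penalties and time-of-day effects are out of
scope). A segment of length $\ell$ metres at $v$ km/h costs
$(\ell/1000)/v \times 60$ minutes. Undirected input segments become two
opposing arcs (one-way streets via an optional `oneway` column), and
origin–destination times are exact Dijkstra shortest paths on the arc
costs. Coordinates are planar metres in whatever projected CRS the caller
uses; no geodesy is performed, since travel time derives from edge
lengths only.

Demand points and facilities are snapped to the nearest network node by
Euclidean distance, with ties broken by smallest node id and a
configurable maximum snap distance; unsnapped points are excluded from
all downstream computation and reported, never silently dropped. The
E2SFCA matrix is truncated at $C$; nearest-facility times are kept
*uncapped*, because mean travel times above the catchment are exactly
what coverage reporting needs. Demand unreachable from every facility is
counted in the beyond-catchment band and excluded (with a logged count)
from mean travel times.

## Reporting conventions

* **Coverage tables** bin population by nearest-facility time into
  half-open bands $(0,10], (10,20], (20,30], >30$ with $t=0$ in the first
  band. Shares are kept unrounded internally and written to one decimal.
* **Regional summaries** report mean, max and sample standard deviation of
  the standardized index, unweighted across demand units by default (a
  population-weighted variant sits behind `weighted = TRUE`), plus
  population totals per index interval $[0,0.25], (0.25,0.5], (0.5,0.75],
  (0.75,1]$.
* **Scenario comparisons** are exact `after − before` differences; share
  deltas are *percentage points*, not relative changes, which is why a
  band can gain population while losing share when the two scenarios
  total differently.

## The synthetic study region

Real census microdata and commercial street networks are rarely
redistributable, so the package ships a seeded generator whose output
exercises every pipeline stage. It emulates the structural features the
analysis depends on, not any particular geography:

* a connected grid road network (`spacing_km` apart) with diagonal
  shortcuts in a fraction of cells, a fraction of edges removed (a
  retained spanning tree guarantees connectivity) so the periphery has
  detours, and road classes assigned by edge-betweenness rank — the most
  central 5% become motorways, then 15% primary, 30% secondary, the rest
  local;
* a population surface mixing Gaussian-kernel urban cores (70% of the
  mass by default) with a uniform rural remainder, integer counts summing
  exactly to the target via largest-remainder rounding, and region labels
  from a nearest-seed spatial partition;
* facilities placed at populated nodes with probability
  $\propto P^{\gamma}$, service levels following local demand (the
  densest sites get multipurpose units), and a reform that closes the
  `n_closures` facilities with the smallest step-1 catchment population —
  the closure pattern that empirically hits rural services first. A
  `random` closure strategy is available for null comparisons.

Everything is deterministic under the spec's seed (integer populations,
fixed iteration order), which the byte-identical-rerun tests rely on.

### Default parameters and why

| parameter | default | rationale |
|-----------|---------|-----------|
| extent, spacing | 280 km, 5 km | a national-scale region (≈78,000 km²) at census-tract-like resolution |
| total population | 10,000,000 | a mainland-Portugal-sized population |
| cores, urban share, σ | 5, 0.70, 10 km | a handful of metropolitan areas holding most of the population |
| facilities, closures | 73, 15 | the emergency-network reform studied: 73 services before, 58 after |
| γ | 1.2 | facility placement concentrated in cores; with the extent above this yields roughly an 86/14 within/beyond-30-min split before reform and 80/20 after, the regime the method is designed to discriminate |
| physicians per level | BES 10, MSES 150, MES 500 | the steep staffing hierarchy of emergency networks: basic units run on a handful of physicians, multipurpose university hospitals on hundreds. This also keeps the accessibility maximum in the metropolitan core, where min–max standardization needs it (see above) |

The generator does **not** emulate coastlines, real administrative
boundaries, census-tract size heterogeneity, or demand elasticity; a
passing test suite shows the *method* behaves correctly under the
structural assumptions, not that any particular real region has these
parameters.

## A worked example

The single-facility instance used throughout the tests: 10 physicians at
one site; 100 people 5 minutes away, 200 at 15 minutes, 500 at 35 minutes.

```{r toy}
nodes <- data.frame(node_id = c("F", "A", "B", "C"),
                    x = c(0, 1, 2, 3) * 1000, y = 0)
edges <- data.frame(from = c("F", "A", "B"), to = c("A", "B", "C"),
                    length_m = c(5, 10, 20) * 1000, speed_kmh = 60,
                    road_class = "local")
net <- load_road_network(nodes, edges)
demand <- load_points(data.frame(
  id = c("d1", "d2", "d3"), x = c(1, 2, 3) * 1000, y = 0,
  population = c(100, 200, 500), region = "R1"), "demand")
fac <- load_points(data.frame(
  id = "H1", x = 0, y = 0, physicians = 10, level = "MES"), "facility")

dn <- snap_to_network(demand, net)
fn <- snap_to_network(fac, net)
ttm <- od_matrix(net, dn, fn, cutoff = 30)
res <- standardize(e2sfca(ttm, demand, fac))
res
```

Step 1 gives $R = 10 / (100 \cdot 1 + 200 \cdot 0.42) = 10/184 \approx
0.05435$; step 2 hands the zone-1 unit the full ratio, the zone-2 unit
$0.42 R$, and the 35-minute unit nothing. The standardized surface is
exactly $(1, 0.42, 0)$, and the population-weighted mean nearest time is
$(100 \cdot 5 + 200 \cdot 15 + 500 \cdot 35)/800 = 26.25$ minutes.

## Problem sizes in the test suite

The oracle-equivalence suites run exhaustive path enumeration on 200
random graphs of at most 8 nodes and compare the vectorised E2SFCA
against a naive double-loop reference on 100 random instances of at most
10 demand points and 5 facilities, both at $10^{-12}$. Monotonicity under
single-facility closure is checked on 50 seeded 121-node regions with 8
facilities each, and the end-to-end determinism and reform-direction
checks run the full default region (3,249 demand units, 73 facilities)
— sizes chosen so the whole suite exercises every property at full
strength while remaining quick on a laptop.

## Known limitations

* One travel mode at fixed class speeds; no congestion (deliberately, to
  keep the before/after comparison about network structure and supply).
* The E2SFCA ignores facility competition beyond the shared catchment
  accounting; three-step variants address this and are out of scope here.
* Min–max standardization couples every score to the best-served unit, as
  discussed above; compare raw indices when a reform touches the maximum.
* Demand is aggregated to centroids; within-tract travel is invisible.
* No facility priority-level weighting: physician counts already carry
  the level hierarchy.
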