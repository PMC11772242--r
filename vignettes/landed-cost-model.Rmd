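---
title: "The landed-cost model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The landed-cost model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcm)
```

`glcm` estimates the field-to-customer cost of internationally traded grain
and oilseed commodities at subnational resolution. This vignette documents
the model itself: its components and assumptions, the parameters that
matter, the numerical conventions, and the choices made where the design
was genuinely open.

## Model structure

The landed cost of commodity $g$ shipped from exporting region $er$ to
importing region $ir$ is

$$\mathrm{LC}_{er,ir,g} = \mathrm{PC}_{er,g} + \mathrm{ST}
  + \mathrm{TC}_{er,ir} + \mathrm{IT}_{er,ir,g},$$

reported throughout as nine additive components: five production inputs
(fertilizer, pesticides, labour, machinery, farm diesel), storage,
transport, border compliance and tariff. All results are *costs*, not
prices: mark-ups, subsidies and equilibrium price formation are outside the
model.

### Production costs

Country-by-commodity input costs are supplied per hectare and converted to
per-tonne values with the regional yield $Y_{r,g}$:

$$\mathrm{PC}_{r,g} = \mathrm{CF} \times
  \frac{\mathrm{PC}_{c,g}\,(\mathrm{USD/ha})}{Y_{r,g}}.$$

The correction factor acknowledges that per-hectare spending is not
constant within a country — high-yielding regions tend to use more input
per hectare. The only structural anchors available are that CF is a
function of the regional and country-median yields and equals one at the
median; we adopt the minimal monotone form satisfying them,

$$\mathrm{CF} = \left(\frac{Y_{r,g}}{\tilde{Y}_{c,g}}\right)^{\gamma},
  \qquad \gamma \in [0,1],\ \text{default } 0.5,$$

with $\tilde{Y}_{c,g}$ the unweighted median over the country's producing
regions. $\gamma = 0$ disables the correction; $\gamma = 1$ makes
per-hectare spending fully proportional to yield (so per-tonne costs become
yield-independent). Because the empirically calibrated form is survey-based
and not part of this package, `production_costs()` also accepts a
user-supplied CF table that overrides the built-in law per region and
commodity.

Storage and upcountry handling before export is a flat charge
(`storage_usd_t`, default 20 USD/t, the midpoint of indicative 11–31 USD/t
values for major exporters), uniform across countries and commodities.
Fixed costs such as land, insurance and financing are deliberately
excluded.

### Transport: generalized-cost routing

Freight moves over five network layers: road, rail, and three maritime
layers (dry bulk, container, general cargo) that use different terminals
and cost structures. Routing minimises the generalized cost

$$\mathrm{GC} = \underbrace{\mathrm{DC}\cdot D + \mathrm{HC}}_{\text{money}}
  + \mathrm{VFTT}\,(T + W) + B,$$

with distance cost rate DC (USD/t/km), handling charges HC (USD/t) at
(un)loading points, ports and rail terminals, travel and waiting time
$T + W$ (h) valued at the country- and mode-specific value of freight
travel time (USD/t/h), and border compliance costs $B$ (USD/t).

Implementation details that affect results:

* **Mode graphs.** The road graph contains region attachments and road
  edges; rail adds rail edges plus road–rail transfers; each maritime graph
  adds one maritime layer plus port transfers, so land access legs are
  always available to reach ports. Rail edges are dropped for pairs whose
  countries lack rail parameters.
* **Edge attribution.** A travel edge takes the mean of its two endpoint
  countries' DC and VFTT (they coincide within a country). A border is
  crossed when an edge joins nodes of different countries; both sides'
  mode-specific $B$ accrue there, covering export and import clearance.
  Transfers charge the HC and dwell time $W$ of the layer being entered or
  left (the non-road side), in the node's country.
* **Search.** One-to-all Dijkstra per origin region and mode. Vertices are
  settled in (distance, lexicographic name) order and cost ties (relative
  tolerance $10^{-9}$) resolve to the lexicographically smallest node
  sequence, making routes fully reproducible. An independent igraph
  cross-check and an exhaustive path-enumeration oracle guard this search
  in the test suite.
* **Mode selection.** The representative mode is the feasible mode with
  the lowest GC; exact ties fall back to the fixed priority road < rail <
  maritime dry bulk < container < general cargo. Disconnected pairs are an
  explicit no-route value, never an error.
* **What is charged.** The trade cost adds only money:
  $\mathrm{TC} = \mathrm{TrC} + B$. VFTT terms select routes but are not
  billed; this is a deliberate reading of the trade-cost definition and is
  worth remembering when comparing transport-cost shares against sources
  that monetise time.

The pre-border transport cost $\mathrm{TrCB}$ — the tariff base's transport
part — sums the monetary transport charges incurred before entering the
importer: for land routes everything up to and including the border-crossing
edge; for maritime routes everything up to and including the discharge
transfer at the importer's port of entry (so that port's handling stays on
the pre-border side, matching a CIF-like tariff base). Importer hinterland
haulage and final unloading are post-border.

### Tariffs and landed-cost assembly

Ad valorem tariffs apply to the at-border value:

$$\mathrm{IT}_{er,ir,g} = \mathrm{avit}_{ec,ic,g}
  \times (\mathrm{PC} + \mathrm{ST} + B + \mathrm{TrCB}).$$

Pairs without a tariff record default to a zero rate. Records are only
created for pairs with a feasible route.

### Radiation downscaling of bilateral trade

Country-level bilateral flows $T_{ec,ic,g}$ are split across region pairs
with a parameter-free radiation model. Import demand within a country
scales with regional population; production and demand weights are
normalized by their country totals so origin and intervening masses are
commensurate:

$$T_{er,ir,g} = T_{ec,ic,g}\,
 \frac{\bar{C}_{ir}\bar{P}_{er}}
 {(\bar{C}_{ir} + \bar{P}_{er,ir})(\bar{C}_{ir} + \bar{P}_{er} + \bar{P}_{er,ir})},$$

where $\bar{P}_{er,ir}$ is the intervening mass: the normalized production
of *other regions of the same exporting country* whose landed cost to $ir$
is strictly lower than this pair's. Three conventions are deliberate:

* the intervening candidate set is country-wide (the exporting country's
  other regions), because the allocation logic is about where within the
  exporting country it is cheaper to source;
* ties in landed cost do not intervene (strict inequality), and a region
  never intervenes against itself;
* the raw utilities do not sum to one, so allocated flows are rescaled
  proportionally to conserve each bilateral total exactly — conservation
  is what makes downstream weighted averages well defined. The test suite
  enforces it to $10^{-9}$ relative.

Regions with zero production get zero weight and hence zero flow; domestic
(same-country) flows are out of scope. Bilateral relations with no
routable, positively weighted pair are dropped with a warning, and the
allocated share of tonnage is reported as a completeness statistic.

### Aggregation metrics

Weighted averages use flow quantities as weights. Quantiles of the
landed-cost distribution use a **left-continuous weighted step quantile**
(the smallest cost whose cumulative weight share reaches $p$, no
interpolation), which matches reading a cumulative supply curve; the
inequality of sourcing costs is $\mathrm{ISC} = (Q_{90} - Q_{10})/Q_{50}$.
The step convention makes ISC exactly zero for uniform costs and invariant
under rescaling; an interpolating convention would give slightly smoother
quantiles on small supplier sets, and can be layered on by the user if
wanted. Geography groupings are user-supplied columns — the package imposes
no region taxonomy.

## Scenario engines

**Input-price shock.** Static pass-through: the fertilizer, pesticides,
farm-diesel and transport components are multiplied (defaults 3.0, 3.0,
1.8, 1.5 — i.e. +200%, +200%, +80%, +50%), quantities and sourcing stay
fixed, and labour, machinery, storage and border are untouched. TrCB
scales with transport. Because tariffs are ad valorem on the shocked base,
they are recomputed by default (`recompute_tariffs = TRUE`); the resulting
interaction mass is allocated proportionally across the three direct
driver contributions so attribution shares sum to one. Without tariffs the
cost sum is linear and single-driver deltas add up exactly — a property the
tests assert.

**Cost-reduction benchmarking.** Four groups are capped independently:
tariff rates and per-tonne production costs at their commodity medians,
border compliance at the global median (border costs are route-, not
commodity-specific), and transport at a distance benchmark. Medians are
unweighted across records with positive flow by default — a median over the
traded universe, with quantity weighting available via `weighted = TRUE`.
The transport benchmark recognises that average cost per tonne-km falls
with distance (hinterland legs are dearer than maritime line-haul), so a
single median would be distance-biased; instead we fit
$\ln(\mathrm{ATC}) = \beta_0 + \beta_1 \ln(D)$ by OLS per coarse mode
(road, rail, maritime — the three maritime layers are pooled) at
country-pair level, and cap each record's transport cost at
$\hat{\mathrm{ATC}}(D)\cdot D$. Values below a benchmark are never raised,
and tariffs are recomputed on the reduced base, so reduced totals are
bounded above by baselines record by record.

**Clustering.** Regions are clustered on their four standardized
savings-share features with `stats::kmeans` (default $k = 6$, 25 restarts,
fixed seed). Because k-means labels are arbitrary, clusters are relabelled
deterministically — ordered by their dominant centroid feature (production,
border, tariff, transport) and then by descending dominant share — so the
same data and seed always produce the same labels. $k$ is configurable;
values around 5–7 give qualitatively similar typologies on synthetic
worlds.

## The synthetic world generator

`generate_world()` produces a complete, internally consistent input bundle
from a seed: planar country geography with Euclidean distances inflated by
mode detour factors (road 1.3, rail 1.2, maritime 1.5); an intra-country
road backbone plus optional density-controlled shortcuts; rail in a subset
of countries; ports in a configurable fraction of countries with ring-plus-
shortcut maritime layers (the ring guarantees connectivity); landlocked
countries connected by road to the nearest foreign port; log-normal
populations, yields, input costs and transport parameters around
realistic magnitudes (e.g. road distance costs near 0.05 USD/t/km versus
maritime near 0.004–0.008 USD/t/km, port dwell near 1.5–2 days); and a
bilateral trade matrix allocated from population-scaled import demand to
surplus producers, capped so no exporter ships more than it produces.

The generator emulates the *schemas and structural invariants* of real
input data, not the world: geography is abstract, trade is not
gravity-calibrated, demand has no elasticities, and costs have no spatial
autocorrelation beyond the country level. Passing tests therefore
demonstrate that the machinery is correct (conservation, additivity,
optimality, determinism), not that any particular real-world number is
reproduced. All draws flow through one seeded generator; the same
configuration and seed reproduce every table exactly.

## Numerical conventions and degenerate inputs

* Additivity of landed-cost components holds to $10^{-9}$; route-cost
  decompositions reconstruct the generalized cost exactly.
* Cost ties in routing and mode selection use a $10^{-9}$ relative
  tolerance; tie-breaks (lexicographic path, fixed mode priority) are
  documented contracts, not implementation accidents.
* Zero or negative yields, negative costs, negative multipliers, empty
  quantile inputs and an importer with zero total population all fail fast
  with errors naming the offending field, region or row.
* Zero-quantity aggregation groups yield `NA` with a warning rather than
  `NaN`. A bilateral relation whose utilities are all zero is an error
  naming the relation.
* Regression benchmarks require at least three country pairs and
  non-degenerate distances per mode; clustering requires at least $k$
  regions with positive savings.

## Problem sizes

The default study world uses 20 countries, roughly 100 regions and 6
commodities — about 450 bilateral relations downscaled to roughly ten
thousand regional flows — which the full pipeline processes in well under
five minutes on one CPU. Unit and property tests run on 2–6-country worlds
and on randomized graphs of at most ten nodes, where exhaustive
path enumeration is feasible as an oracle.

## Known limitations

* Static costs only: no supplier switching, no supply or demand response,
  no equilibrium prices, no congestion or capacity constraints.
* Import demand scales with population, which misrepresents countries
  importing mainly feed grain.
* Domestic sourcing is not modelled; all statistics describe imported
  grain.
* The built-in CF power law is a structural stand-in calibrated only by
  its anchor and monotonicity; use the override table when survey-based
  factors are available.
* Transport parameters are required inputs per country and mode; the
  package does not gap-fill missing countries.
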