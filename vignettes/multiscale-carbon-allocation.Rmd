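---
title: "Multi-scale source–sink carbon allocation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale source-sink carbon allocation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carballoc)
```

## The model

`carballoc` simulates one day of carbon allocation in a woody plant
represented as a multi-scale tree graph (MTG). Leaves assimilate carbon
(sources); fruits, growing shoots, wood and the root system demand it
(sinks). The daily flow from source $i$ to sink $j$ is

$$F_{ij} \;=\; \mathrm{ACP}_i \,
  \frac{\mathrm{Demand}_j \, f(d_{ij}, h)}
       {\sum_k \mathrm{Demand}_k \, f(d_{ik}, h)},
  \qquad f(d, h) = \frac{1}{(1 + d)^h},$$

where $\mathrm{ACP}_i$ is the carbon available at source $i$ (g C),
$\mathrm{Demand}_j$ the total carbon demand of sink $j$ (g C), $d_{ij}$
the topological distance between the two components (metres) and $h \ge
0$ an empirical *friction* parameter. Each source distributes exactly its
supply (the weights are normalized per source), so carbon is conserved by
construction. A sink receiving more than its demand keeps the surplus in
a reserve pool, which is re-offered as supply on the following day; no
redistribution happens within a day. $h = 0$ removes the effect of
distance entirely (a *common assimilate pool*); large $h$ concentrates
each source's carbon on its nearest sinks. Because $f$ adds 1 metre to
the distance before exponentiating, the unit of length matters: all
internal lengths and coordinates are metres, and the file readers accept
a unit flag (`m`, `cm`, `mm`) to convert on input.

Sinks along the path between a source and a sink do not intercept the
flow: two equal sinks at equal distance from a source receive the same
amount regardless of what lies between. This is a deliberate limit of
the formalism, which buys the model its single tunable parameter.

## Scales of representation

The plant is stored once at the metamer (M) scale — one vertex per node +
internode with its attached leaf and/or fruit — plus a one-vertex plant
container, and the root system as a single opaque `root_compartment`
vertex below the trunk base. Coarser *working scales* are built by
grouping metamers into connected subtrees:

* **GU** — growth units, read from a per-metamer label;
* **TBS** — the trunk (branching order 0), each first-order branch's
  woody part, and each current-year leafy shoot;
* **BR1** — the trunk and each entire first-order branch subtree, shoots
  included;
* **FU** — fruiting units: each maximal section of one-year-old wood
  with the current-year shoots it bears; all older wood forms one
  supporting group;
* any user rule mapping metamers to connected groups.

`build_scale()` inserts exactly one working scale between the plant and
metamer scales. Two independently defined groupings (say GU inside TBS)
are not nested in general, so a tree carries at most one built scale and
each working scale is built from the same base tree; this mirrors how
simulations are actually run — one scale at a time — and keeps the
component/complex invariants trivially checkable. Demands, supplies and
masses are up-scaled by summation (totals are conserved exactly);
allocated carbon is down-scaled proportionally to the finer-level
demands, first to metamers and then to the organs inside each metamer.

Classification choices where the scale definitions are underdetermined:
branching order increments at every `+` (branching) edge from the trunk
base, the standard MTG convention. A "leafy shoot" is a maximal
current-year subtree bearing at least one leaf; leafless current-year
growth stays with its supporting wood. A tree with no wood older than
the current year degenerates to a single fruiting unit. Epicormic shoots
are not distinguished from proleptic ones — they classify as shoots and
reuse the proleptic Gompertz parameters, as no separate parameter set is
available.

## Distances

The distance between two components is measured along the topology
between their barycentres. At the metamer scale the base of a vertex is
the top of its parent (the tree root reads its base from its complex)
and the barycentre is the midpoint of base and top. At a coarse scale
the base of a component is the base of its *base component* (the one
whose parent lies outside the group), its length is the sum of its
components' lengths, and its barycentre is the length-weighted mean of
the component barycentres. The *semi-length* is the Euclidean distance
from base to barycentre.

Given two vertices, the greatest common ancestor (GCA) of their
root-paths is found; the distance is the sum of the two semi-lengths and
of the lengths of the path elements strictly between each vertex and the
GCA. When the GCA is neither endpoint the two path elements directly
borne on the GCA need not share a base point (ramifications insert at
different positions along a coarse component), and the Euclidean
distance between their bases is added; the GCA's own length does not
contribute. When the GCA is one of the endpoints the distance is just
the internal lengths plus the two semi-lengths. Self-distance is zero,
so a component that is both source and sink weights itself with $f = 1$
— the strongest possible self-attraction, consistent with the
common-pool limit.

Two conventions deserve a note. The length of a *branched* coarse
component entering the path sum is its total wood length (sum over
components); an entry-to-exit path length would be smaller for branched
groups. The choice is consistent with using coarse length as the
aggregate of its parts everywhere else, and the distance tests cover it
through the independent path-walk oracle at every scale. And the base
gap is measured as the straight-line 3-D distance between base points,
the natural metric when components insert at different heights on their
common ancestor.

`distance_matrix()` caches root paths and cumulative lengths, so the
all-pairs cost is near-quadratic in the number of components at the
working scale, which is the point of coarsening: the component counts
drop by roughly one order of magnitude from M to GU and another towards
BR1/FU.

## Demands, supplies, respiration

Organ biomasses are initialized from allometry: old wood as cylinder
volume × density (700 kg m⁻³); leaves as area × 0.08 kg m⁻²; fruits at
8 g dry weight each; current-year shoot stems from a generalized linear
model on whole-shoot length (cm) and cumulated thermal time,
$\exp(a + b\log L + c\,\mathrm{GDD} + d\,L + e \log(L \cdot
\mathrm{GDD}))$ grams, distributed over the shoot's metamers in
proportion to metamer length. The GLM is treated as a stem-mass
allometry (leaf mass is booked separately from leaf area); the root
compartment starts at zero recorded mass because its demand is
ratio-driven rather than mass-driven.

The daily dry-matter demand of an organ is

$$\mathrm{DM\_Demand}_j = W_j \times
  \mathrm{activity}(\mathrm{GDD})_{\mathrm{organ}} \times
  \mathrm{GDD}_{\mathrm{day}},$$

with $W_j$ the organ dry weight and activity the maximum potential
relative growth rate per degree-day. Fruits and shoots use the
normalized derivative of a Gompertz potential-growth curve
$W(\mathrm{GDD}) = a e^{b e^{c\,\mathrm{GDD}}}$, evaluated in the ratio
form and algebraically equal to $b\,c\,e^{c\,\mathrm{GDD}}$ (both $b$
and $c$ are negative, so the activity is positive and declines with
thermal time; the package asserts the two forms agree to 1e-12). Old
wood uses a constant activity of 3.1e-5 g g⁻¹ °Cd⁻¹. The narrative
around that calibration could also support a GDD-dependent log-linear
slope; the constant reading is implemented and isolated in a single
parameter, so a user can supply a function of GDD through the leaf-style
lookup mechanism if needed. Leaves use a lookup table keyed by GDD,
linearly interpolated and clipped to the admissible range [0, 1.9e-3];
the published table contents are not available, so the default is a flat
mid-range 1e-3 — explicitly a placeholder to be replaced per orchard.
Root demand is the total vegetative (stem + leaf) dry-matter demand
divided by the shoot:root growth ratio 4.5; fruit and old-wood demand
are excluded from the numerator since the ratio describes vegetative
growth partitioning. Thermal time accumulates daily mean temperature
above a 4.5 °C base, floored at zero.

Dry-mass demands are converted to carbon with the dry-mass:carbon ratio
2.105263158 g DM per g C, so demands and supplies (g C) are
commensurate; allocated carbon converts back with the same ratio when
masses are updated.

Maintenance respiration is dry mass × a per-organ coefficient × a Q10
factor averaged over the day's temperatures; growth respiration is a
coefficient times (maintenance + dry-matter demand); the total demand of
an organ is the sum of all three. The respiration coefficients shipped
as defaults are zeros with QualiTree-style placeholder values documented
in `species_params()` — every computation that asserts numbers sets them
explicitly. Demand is pooled: when supply is short, maintenance takes no
priority over growth; the allocated carbon is split across the
dry-matter and respiration shares in proportion to their demands.

Supplies are per-leaf daily assimilation totals (g C day⁻¹), read from a
table keyed by leaf-bearing metamer — the interface where any radiative
and photosynthesis model plugs in. Negative net values are clipped to
zero with a reported total. At coarse scales supplies are up-scaled like
any other property and act from the coarse component's barycentre, the
same position every other property of the component uses.

## The synthetic generator

`generate_tree()` emulates the architecture class the model targets: a
vertical trunk of one growth unit per year, first-order branches on the
older trunk growth units (Poisson counts), one-year-old wood sections
bearing a fixed number of current-year leafy shoots plus a terminal
extension, normal shoot lengths (16 ± 4 cm), 2 cm metamers, 30 cm²
leaves, and one fruit on 60 % of shoots, inserted at the shoot base.
Defaults give trees of a few hundred metamers and roughly 1 m height, so
metre-scale distances and the default neighbourhood radii are
meaningful. All draws come from fixed-offset substreams of a single
seed, so adding a feature never perturbs earlier draws and the same seed
always yields the identical tree. The companion light stub assigns each
leaf `area × 6 g C m⁻² × exp(−k · depth)` with depth measured from the
highest leaf (k = 0.5 m⁻¹ by default).

What the generator does *not* emulate: biomechanical bending, realistic
Markovian branching statistics, within-shoot leaf-area gradients,
multi-year carry-over of reserves, or radiative transfer with real sky
conditions. Tests passing on these trees therefore demonstrate the
correctness of the graph machinery, the distance algebra and the
allocation arithmetic — not the fidelity of any particular orchard
prediction, which requires measured tree structures and a calibrated
light model through the supply interface.

## Numerical choices

* Allocation weights are computed in log space with a per-source maximum
  subtracted before exponentiation, so the nearest-sink limit (h of 200
  and beyond) is exact instead of overflowing to `NaN`.
* Carbon conservation (per-source outflow = supply; growth + reserves =
  total supply) is asserted at 1e-9 relative tolerance; in practice it
  holds at machine precision.
* With h = 0 the per-organ allocation is analytically independent of the
  working scale (the kernel is constant and down-scaling is
  demand-proportional); the suite asserts identity across all five
  scales at 1e-9 and zero CV(RMSE). This is the strongest cross-scale
  correctness check available without field data.
* Degenerate inputs are resolved, not crashed on: all-zero demand with
  positive supply routes everything to reserves with a warning; a
  component allocated carbon with zero demand routes it to its reserve;
  a zero-length group (the root compartment) takes equal weights for its
  barycentre; correlation over zero-variance comfort indices is reported
  as `NA` and flagged.
* Iteration order is ascending vertex id everywhere, so runs are
  bit-reproducible and invariant to relabelling (asserted by a
  permutation test).
* Distribution comparison z-scores each sample by default (min–max is
  available), bins on a shared 20-bin equal-width grid over the pooled
  range, and compares relative frequencies; the bin count is a
  parameter and reported alongside.
* Fruit-competition correlations pool all fruits per radius (Pearson by
  default, Spearman available), with the significance threshold divided
  by the number of radii (11 by default, i.e. 0.05/11).

## Problem sizes

The shipped test-suite and the acceptance script run on synthetic trees
of roughly 250–400 metamers — ten trees and a hundred tree/h/scale
configurations for conservation, 1200+ random vertex pairs per run for
the distance oracle, and all five scales for the invariance checks.
These sizes were chosen to exercise every code path (multi-GU branches,
branched coarse components, fruit-bearing and barren shoots) while
keeping a full run in tens of seconds; the algorithms themselves have no
size-specific constants, and the distance caching is what makes
coarse-scale runs on multi-thousand-metamer trees practical.

## Known limitations

* Single-day steps, no within-day sub-stepping; multi-day runs chain
  `run_day()` with the returned reserves and updated masses, but no new
  metamers are created.
* No interception of carbon by intermediate sinks along the transport
  path (inherent to the formalism).
* The root system is one opaque compartment; no soil, water or nutrient
  interactions.
* The amapmod text dialect encodes base (plant + metamer) trees only;
  built scales travel through the tabular dialect or are rebuilt from
  properties, which matches how published input files encode growth-unit
  membership — as per-vertex features, mapped through the reader's
  property-name configuration.
* Respiration and leaf-activity defaults are placeholders; quantitative
  use requires setting them from a calibration.
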