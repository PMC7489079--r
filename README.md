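# carballoc

Multi-scale source–sink carbon allocation on tree graphs.

## What problem this solves

Predicting how the carbon a tree assimilates each day is shared among
its fruits, shoots, wood and roots requires knowing *where* sources and
sinks sit on the plant: phloem transport makes nearby sinks better
competitors than distant ones. Functional–structural models that resolve
every metamer capture this but scale badly — all-pairs distance
computation is quadratic in the number of components — while coarse
models (whole branches, fruiting units) are fast but blur the very
distances that drive the outcome. `carballoc` is for plant modellers who
want both ends of that trade-off in one framework: it represents a plant
as a multi-scale tree graph (MTG), lets you run the *same* allocation
model at the metamer (M), growth-unit (GU), trunk/branch/shoot (TBS),
first-order-branch (BR1) or fruiting-unit (FU) scale — or any custom
connected grouping — and quantifies how the choice of scale changes the
predicted organ growth.

## The model

Carbon moves from each source $i$ (leaf supply $\mathrm{ACP}_i$, g C) to
every sink $j$ (demand $\mathrm{Demand}_j$, g C) as

$$F_{ij} = \mathrm{ACP}_i\,
  \frac{\mathrm{Demand}_j\,(1+d_{ij})^{-h}}
       {\sum_k \mathrm{Demand}_k\,(1+d_{ik})^{-h}}$$

where $d_{ij}$ is the topological distance (metres) between component
barycentres, computed through their greatest common ancestor, and $h$ is
an empirical sap-friction parameter: $h=0$ is a common assimilate pool,
large $h$ confines carbon near its source. Sink demands follow organ
dry mass × a thermal-time-dependent sink activity (normalized Gompertz
derivative for fruits and shoots, a constant for old wood, a lookup
table for leaves) × the day's degree-days, plus Q10 maintenance and
growth respiration. Sinks never exceed their demand; surpluses go to a
reserve pool re-offered the next day. Demands and supplies are up-scaled
to a coarse working scale by summation, and allocated carbon is
down-scaled proportionally to demand, so totals are conserved exactly at
every scale.

## Worked example

```r
library(carballoc)

cf   <- synth_config(seed = 42)                  # apple-like synthetic tree
tree <- init_biomass(generate_tree(cf), gdd_cum = 800)
tree
#> Multi-scale tree graph
#>   scale 1 (plant): 1 vertices
#>   scale 2 (M): 325 vertices
#>   organs: 558 (biomass initialized)

supply <- load_supply(tree, generate_supply(tree, cf))
res_M  <- run_day(tree, supply, scale_name = "M", h = 8,
                  gdd_cum = 800, gdd_day = 10)
res_M
#> Carbon allocation result
#>   scale: M, h = 8
#>   total supply: 3.169 g C, total demand: 2.298 g C
#>   growth-allocated: 2.205 g C, to reserves: 0.9641 g C
#>   fruits: 21, mean dry-mass increment: 0.1715 g

tree_gu <- build_scale(tree, "GU")               # same model, coarser scale
res_GU  <- run_day(tree_gu, supply, scale_name = "GU", h = 8,
                   gdd_cum = 800, gdd_day = 10)
cmp <- cross_scale_compare(res_GU, res_M, tree_gu, "GU")
sprintf("GU vs M: RMSE = %.4g g, CV(RMSE) = %.3f", cmp$rmse, cmp$cv_rmse)
#> "GU vs M: RMSE = 0.005128 g, CV(RMSE) = 0.030"

scale_table(tree)
#>   tree scale n_components   pct_of_M
#> 1 tree     M          325 100.000000
#> 2 tree    GU           43  13.230769
#> 3 tree   TBS           38  11.692308
#> 4 tree   BR1           13   4.000000
#> 5 tree    FU           11   3.384615
```

Reading the numbers: on this 325-metamer tree the leaves assimilate
3.17 g C on the simulated day against a total sink demand of 2.30 g C;
with friction h = 8 most sinks are served by nearby sources, 2.21 g C
goes to growth and 0.96 g C ends up in reserves of sinks that were
over-supplied. Each of the 21 fruits gains on average 0.17 g dry mass.
Re-running the identical day at the GU scale (43 components instead of
325) shifts per-component mean fruit growth by a CV(RMSE) of 3 % — the
kind of accuracy/cost trade-off the package is built to measure. With
h = 0 the allocation is provably identical across all five scales, a
property the test suite asserts at 1e-9.

Real trees enter through `read_mtg()` (a documented subset of the classic
AMAPmod MTG text format, or a tabular CSV interchange), and measured
per-leaf assimilation through `load_supply()`; the fruit-competition
neighbourhood analysis is `comfort_index_correlation()` and distribution
comparison is `distribution_rmse()`. A thin CLI with `synth`, `scales`,
`distances`, `run` and `neighbourhood` subcommands is installed at
`exec/carballoc`.

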