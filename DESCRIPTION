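Package: carballoc
Title: Multi-Scale Source-Sink Carbon Allocation on Tree Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates within-plant carbon allocation and organ growth on
    multi-scale tree graphs (MTG). A plant is represented at user-defined
    nested topological scales (metamer, growth unit, trunk/branch/shoot,
    first-order branch, fruiting unit); carbon moves from sources (leaves)
    to sinks (fruits, shoots, wood, roots) as a function of sink demand,
    source supply and topological distance raised to an empirical friction
    parameter. Includes readers and writers for a classic MTG text dialect
    and a tabular interchange format, greatest-common-ancestor distance
    computation with barycentre geometry, Gompertz-based organ sink
    activities driven by growing degree days, up- and down-scaling of
    carbon state between scales, a deterministic generator of apple-like
    synthetic trees, and analyses of cross-scale consistency and fruit
    competition neighbourhoods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
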