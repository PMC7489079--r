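# minimal state builder for direct allocate() tests
mk_state <- function(ids, demand, supply) {
  st <- data.frame(vertex = ids, dm_demand = demand, resp_demand = 0,
                   demand = demand, supply = supply,
                   stringsAsFactors = FALSE)
  rownames(st) <- ids
  st
}
mk_dist <- function(ids, m) {
  dimnames(m) <- list(ids, ids)
  m
}

test_that("a single source fully supplies a single sink at any h", {
  ids <- c("snk", "src")
  D <- mk_dist(ids, matrix(c(0, 2, 2, 0), 2))
  for (h in c(0, 1, 8, 200)) {
    al <- allocate(D, mk_state(ids, c(5, 0), c(0, 1)), h)
    expect_equal(unname(al$received[["snk"]]), 1.0)
    expect_equal(unname(al$reserve[["snk"]]), 0)
  }
})

test_that("equidistant equal-demand sinks split the supply at any h", {
  ids <- c("a", "b", "src")
  D <- mk_dist(ids, matrix(c(0, 4, 2,
                             4, 0, 2,
                             2, 2, 0), 3, byrow = TRUE))
  for (h in c(0, 0.5, 4, 16)) {
    al <- allocate(D, mk_state(ids, c(1, 1, 0), c(0, 0, 1)), h)
    expect_equal(unname(al$received[c("a", "b")]), c(0.5, 0.5))
  }
})

test_that("h = 0 reduces to the common assimilate pool closed form", {
  # two sources ACP = {1, 1}, sinks with demands {1, 3}: every sink gets
  # demand_j * sum(ACP) / sum(demand)
  ids <- c("s1", "s2", "p", "q")
  D <- mk_dist(ids, matrix(c(0, 1, 2, 9,
                             1, 0, 5, 1,
                             2, 5, 0, 3,
                             9, 1, 3, 0), 4, byrow = TRUE))
  al <- allocate(D, mk_state(ids, c(1, 3, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(unname(al$received[c("s1", "s2")]), c(0.5, 1.5))
})

test_that("h -> infinity sends each source's carbon to its nearest sink", {
  ids <- c("near", "far", "src")
  D <- mk_dist(ids, matrix(c(0, 1, 0.4,
                             1, 0, 1.1,
                             0.4, 1.1, 0), 3, byrow = TRUE))
  al <- allocate(D, mk_state(ids, c(1, 1, 0), c(0, 0, 1)), 200)
  expect_gt(unname(al$received[["near"]]), 1 - 1e-9)
})

test_that("the nearer sink's share is non-decreasing in h and tends to one", {
  ids <- c("near", "far", "src")
  D <- mk_dist(ids, matrix(c(0, 1, 0.3,
                             1, 0, 0.9,
                             0.3, 0.9, 0), 3, byrow = TRUE))
  hs <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 200)
  shares <- vapply(hs, function(h) {
    al <- allocate(D, mk_state(ids, c(1, 1, 0), c(0, 0, 1)), h)
    unname(al$received[["near"]])
  }, numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
  expect_equal(shares[1], 0.5)
  expect_gt(shares[length(hs)], 1 - 1e-9)
})

test_that("sinks never exceed demand; surplus goes to reserves; carbon is conserved", {
  ids <- c("s", "src")
  D <- mk_dist(ids, matrix(c(0, 1, 1, 0), 2))
  al <- allocate(D, mk_state(ids, c(0.3, 0), c(0, 1)), 2)
  expect_equal(unname(al$growth_alloc[["s"]]), 0.3)
  expect_equal(unname(al$reserve[["s"]]), 0.7)
  # all demands zero: everything to the source's own reserve, with warning
  expect_warning(
    al0 <- allocate(D, mk_state(ids, c(0, 0), c(0, 1)), 2),
    "reserves")
  expect_equal(unname(al0$reserve[["src"]]), 1)
})

test_that("up-scaled states are brute-force sums over components", {
  fx <- apple_fixture(seed = 13)
  org <- organ_demand(fx$tree, species_params(), 800, 10)
  org <- respiration_demand(org, 20, species_params())
  stM <- carbon_state(fx$tree, org, fx$supply)
  tg <- build_scale(fx$tree, "GU")
  up <- upscale_state(tg, stM, "GU")
  for (I in up$vertex) {
    comp <- components_of(tg, I)
    for (cc in c("demand", "supply", "dm_demand")) {
      expect_equal(up[I, cc], sum(stM[comp, cc]), tolerance = 1e-12)
    }
  }
  # totals invariant across scales
  expect_equal(sum(up$demand), sum(stM$demand))
  expect_equal(sum(up$supply), sum(stM$supply))
  # single-component complexes keep their values (identity rule)
  ti <- build_scale(fx$tree, scale_spec("I", rule = function(tr) {
    vs <- vertices_at(tr, finest_scale(tr)); stats::setNames(vs, vs)
  }))
  upi <- upscale_state(ti, stM, "I")
  expect_equal(sort(unname(upi$demand)), sort(unname(stM$demand)))
})

test_that("down-scaling splits by relative demand and conserves totals", {
  fx <- apple_fixture(seed = 13)
  res <- run_day(fx$tree, fx$supply, scale_name = "M", h = 4,
                 gdd_cum = 800, gdd_day = 10)
  org <- res$organs
  # organ allocations within a metamer sum to the metamer allocation
  per_met <- tapply(org$allocated, org$vertex, sum)
  for (v in names(res$metamer_alloc)) {
    expect_equal(unname(res$metamer_alloc[[v]]),
                 if (v %in% names(per_met)) unname(per_met[[v]]) else 0,
                 tolerance = 1e-9)
  }
  # a three-organ metamer with demands {2,1,1} and allocation 2
  toy <- data.frame(vertex = "m", organ = c("fruit", "leaf", "internode"),
                    dry_mass = 1, dm_demand = c(2, 1, 1),
                    total_demand = c(2, 1, 1), stringsAsFactors = FALSE)
  tree <- chain_tree(1)
  al <- list(growth_alloc = c(m = 2), reserve = c(m = 0))
  stM <- data.frame(vertex = "m", demand = 4, supply = 0)
  rownames(stM) <- "m"
  down <- downscale_allocation(tree, al, stM, toy, "M")
  expect_equal(down$organ_alloc$allocated, c(1, 0.5, 0.5))
})

test_that("mass updates convert allocated carbon to dry matter", {
  org <- data.frame(vertex = "m", organ = "fruit", dry_mass = 0.008,
                    dm_demand = 0.4, total_demand = 0.4, allocated = 0.4,
                    stringsAsFactors = FALSE)
  tree <- chain_tree(1)
  tree$organs <- data.frame(vertex = "m", organ = "fruit",
                            dry_mass = 0.008, stringsAsFactors = FALSE)
  sp <- species_params()
  up <- update_masses(tree, org, sp)
  # fully satisfied dry-matter demand: increment = demand in dry mass
  expect_equal(up$organs$dm_increment, 0.4 * sp$dry_mass_to_C_mass)
  expect_equal(up$tree$organs$dry_mass,
               0.008 + 0.4 * sp$dry_mass_to_C_mass / 1000)
  # zero allocation, zero increment
  org$allocated <- 0
  expect_equal(update_masses(tree, org, sp)$organs$dm_increment, 0)
})

test_that("run_day composes the stage operations exactly", {
  fx <- apple_fixture(seed = 17, n_trunk_gus = 3)
  sp <- species_params(maintenance_coeff = c(wood = 2e-5, internode = 1e-4,
                                             leaf = 1e-4, fruit = 5e-5,
                                             root = 0),
                       growth_resp_coeff = 0.2)
  res <- run_day(fx$tree, fx$supply, sp, scale_name = "M", h = 8,
                 gdd_cum = 800, gdd_day = 10, temperature_c = 22)
  # manual composition
  org <- respiration_demand(organ_demand(fx$tree, sp, 800, 10), 22, sp)
  st <- carbon_state(fx$tree, org, fx$supply)
  geom <- annotate_geometry(fx$tree, "M")
  act <- st$vertex[st$supply > 0 | st$demand > 0]
  D <- distance_matrix(fx$tree, geom, "M", act, act)
  al <- allocate(D, st, 8)
  down <- downscale_allocation(fx$tree, al, st, org, "M")
  up <- update_masses(fx$tree, down$organ_alloc, sp)
  expect_equal(res$organs$allocated, up$organs$allocated, tolerance = 1e-12)
  expect_equal(res$organs$dm_increment, up$organs$dm_increment,
               tolerance = 1e-12)
  # determinism: bit-identical rerun
  res2 <- run_day(fx$tree, fx$supply, sp, scale_name = "M", h = 8,
                  gdd_cum = 800, gdd_day = 10, temperature_c = 22)
  expect_identical(res$organs, res2$organs)
})

test_that("source conservation and global closure hold on whole-tree runs", {
  fx <- apple_fixture(seed = 19)
  for (h in c(0, 2, 8)) {
    res <- run_day(fx$tree, fx$supply, scale_name = "M", h = h,
                   gdd_cum = 800, gdd_day = 10)
    out <- rowSums(res$flows)
    expect_equal(unname(out),
                 unname(res$state[names(out), "supply"]), tolerance = 1e-9)
    expect_equal(sum(res$organs$allocated) + sum(res$reserve),
                 sum(res$state$supply), tolerance = 1e-9)
  }
})

test_that("with h = 0 per-organ growth is identical across all five scales", {
  fx <- apple_fixture(seed = 23)
  resM <- run_day(fx$tree, fx$supply, scale_name = "M", h = 0,
                  gdd_cum = 800, gdd_day = 10)
  for (sn in c("GU", "TBS", "BR1", "FU")) {
    tg <- build_scale(fx$tree, sn)
    rc <- run_day(tg, fx$supply, scale_name = sn, h = 0,
                  gdd_cum = 800, gdd_day = 10)
    expect_equal(rc$organs$allocated, resM$organs$allocated,
                 tolerance = 1e-9)
    expect_equal(rc$organs$dm_increment, resM$organs$dm_increment,
                 tolerance = 1e-9)
  }
})

test_that("organ allocations are equivariant under vertex relabelling", {
  fx <- apple_fixture(seed = 29, n_trunk_gus = 3)
  res <- run_day(fx$tree, fx$supply, scale_name = "M", h = 8,
                 gdd_cum = 800, gdd_day = 10)
  # relabel: prefix swap keeps ids unique but changes the sort order
  relab <- function(x) ifelse(is.na(x), x,
                              paste0(ifelse(substr(x, 1, 1) == "v", "z", "a"),
                                     x))
  t2 <- fx$tree
  t2$vertex <- relab(t2$vertex)
  names(t2$scale) <- names(t2$parent) <- names(t2$edge) <-
    names(t2$complex) <- t2$vertex
  t2$parent[] <- relab(t2$parent)
  t2$complex[] <- relab(t2$complex)
  rownames(t2$props) <- relab(rownames(t2$props))
  t2$organs$vertex <- relab(t2$organs$vertex)
  ord <- order(t2$vertex)
  t2$vertex <- t2$vertex[ord]
  t2$scale <- t2$scale[t2$vertex]; t2$parent <- t2$parent[t2$vertex]
  t2$edge <- t2$edge[t2$vertex]; t2$complex <- t2$complex[t2$vertex]
  t2$props <- t2$props[t2$vertex, ]
  validate_mst(t2)
  s2 <- stats::setNames(fx$supply, relab(names(fx$supply)))
  res2 <- run_day(t2, s2, scale_name = "M", h = 8,
                  gdd_cum = 800, gdd_day = 10)
  key1 <- paste(relab(res$organs$vertex), res$organs$organ)
  key2 <- paste(res2$organs$vertex, res2$organs$organ)
  expect_equal(res2$organs$allocated[match(key1, key2)],
               res$organs$allocated, tolerance = 1e-9)
})

test_that("excess carbon is stored and re-offered as next-day supply", {
  # two metamers: a leaf-bearing source and a small fruit sink
  rows <- data.frame(
    vertex_id = c("m1", "m2"), parent_id = c(NA, "m1"),
    edge_type = c(NA, "<"), organ_type = "internode", year = c(1, 1),
    top_x = 0, top_y = 0, top_z = c(0.1, 0.2), radius = 0.005,
    length = c(0.1, 0.1), leaf_area = c(0.01, 0), has_fruit = c(0, 1),
    stringsAsFactors = FALSE)
  tree <- init_biomass(mst_from_table(rows), species_params(), 500)
  sup <- stats::setNames(c(1, 0, 0), c("m1", "m2", "ROOT0"))
  day1 <- run_day(tree, sup, scale_name = "M", h = 1,
                  gdd_cum = 500, gdd_day = 5)
  expect_gt(sum(day1$reserve), 0)      # supply exceeded total demand
  # day 2 without fresh supply: reserves alone drive further growth
  zero <- stats::setNames(rep(0, 3), names(sup))
  day2 <- run_day(day1$tree, zero, scale_name = "M", h = 1,
                  gdd_cum = 505, gdd_day = 5, reserve = day1$reserve)
  expect_equal(sum(day2$state$supply), sum(day1$reserve), tolerance = 1e-12)
  expect_gt(sum(day2$organs$allocated), 0)
})
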