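sp0 <- species_params()   # respiration defaults are zero coefficients

test_that("biomass initialization follows the allometric rules", {
  rows <- data.frame(
    vertex_id = c("w1", "s1", "s2"), parent_id = c(NA, "w1", "s1"),
    edge_type = c(NA, "<", "<"), organ_type = "internode",
    year = c(1, 2, 2), top_x = 0, top_y = 0, top_z = c(1, 1.05, 1.1),
    radius = c(0.01, 0.002, 0.002), length = c(1, 0.05, 0.05),
    leaf_area = c(0, 0.01, 0), has_fruit = c(0, 0, 1),
    stringsAsFactors = FALSE)
  tree <- init_biomass(mst_from_table(rows), sp0, gdd_cum = 500)
  org <- tree$organs
  m <- function(v, o) org$dry_mass[org$vertex == v & org$organ == o]
  # cylinder r = 0.01 m, length 1 m, density 700 kg/m3
  expect_equal(m("w1", "wood"), 0.21991148575128552, tolerance = 1e-12)
  # leaf: 0.01 m2 x 0.08 kg/m2
  expect_equal(m("s1", "leaf"), 8e-4, tolerance = 1e-12)
  # fruit: 8 g initial dry weight
  expect_equal(m("s2", "fruit"), 0.008)
  # shoot GLM on the whole 10 cm shoot at GDD 500, split across 2 metamers
  glm_g <- 0.2963412435932836          # frozen direct evaluation
  expect_equal(m("s1", "internode") + m("s2", "internode"), glm_g / 1000,
               tolerance = 1e-9)
  expect_equal(m("s1", "internode"), m("s2", "internode"))  # equal lengths
  # root compartment organ exists with zero mass
  expect_equal(m("ROOT0", "root"), 0)
})

test_that("shoot dry weight matches the direct formula and rejects bad input", {
  expect_equal(shoot_dry_weight(10, 500, sp0), 0.2963412435932836,
               tolerance = 1e-12)
  expect_equal(shoot_dry_weight(20, 800, sp0), 0.6012235975774973,
               tolerance = 1e-12)
  expect_error(shoot_dry_weight(0, 500, sp0), "positive")
})

test_that("the printed Gompertz ratio equals its analytic simplification", {
  gdd <- seq(0, 3000, by = 25)
  for (organ in c("fruit", "shoot")) {
    pp <- sp0$gompertz[[organ]]
    expect_equal(gompertz_rgr(gdd, pp),
                 pp[["b"]] * pp[["c"]] * exp(pp[["c"]] * gdd),
                 tolerance = 1e-12)
  }
  expect_equal(gompertz_rgr(0, sp0$gompertz$fruit), 0.00509184,
               tolerance = 1e-9)
  # c -> 0 limit collapses the activity to b*c -> 0
  expect_equal(gompertz_rgr(100, c(a = 10, b = -3, c = -1e-12)), -3e-12 *
                 exp(-1e-10), tolerance = 1e-6)
})

test_that("the Gompertz activity is the derivative of the log potential curve", {
  h <- 0.01
  for (organ in c("fruit", "shoot")) {
    pp <- sp0$gompertz[[organ]]
    logW <- function(g) log(pp[["a"]] * exp(pp[["b"]] * exp(pp[["c"]] * g)))
    for (g in seq(0, 3000, by = 250)) {
      num <- (logW(g + h) - logW(g - h)) / (2 * h)
      expect_equal(gompertz_rgr(g, pp), num, tolerance = 1e-6)
    }
  }
})

test_that("organ demands follow mass x activity x daily thermal time", {
  rows <- data.frame(
    vertex_id = c("w1", "s1"), parent_id = c(NA, "w1"),
    edge_type = c(NA, "<"), organ_type = "internode", year = c(1, 2),
    top_x = 0, top_y = 0, top_z = c(1, 1.1), radius = c(0.01, 0.002),
    length = c(1, 0.1), leaf_area = c(0, 0.01), has_fruit = c(0, 1),
    stringsAsFactors = FALSE)
  tree <- init_biomass(mst_from_table(rows), sp0, gdd_cum = 500)
  org <- organ_demand(tree, sp0, gdd_cum = 0, gdd_day = 10)
  d <- function(o) org$dm_demand_dm[org$organ == o]
  # fruit of 8 g at GDD 0: 8 x 0.00509184 x 10 in dry-mass units
  expect_equal(d("fruit"), 8 * 0.00509184 * 10, tolerance = 1e-9)
  # old wood: constant activity
  expect_equal(d("wood"),
               0.21991148575128552 * 1000 * 3.1e-5 * 10, tolerance = 1e-9)
  # root demand = vegetative (stem + leaf) demand / 4.5
  veg <- sum(org$dm_demand_dm[org$organ %in% c("internode", "leaf")])
  expect_equal(d("root"), veg / 4.5, tolerance = 1e-12)
  # conversion to carbon units
  expect_equal(org$dm_demand, org$dm_demand_dm / sp0$dry_mass_to_C_mass)
  # no thermal time, no demand
  org0 <- organ_demand(tree, sp0, gdd_cum = 0, gdd_day = 0)
  expect_equal(org0$dm_demand, rep(0, nrow(org0)))
  # demand is homogeneous of degree 1 in organ mass
  tree2 <- tree
  tree2$organs$dry_mass <- tree2$organs$dry_mass * 3
  org3 <- organ_demand(tree2, sp0, gdd_cum = 0, gdd_day = 10)
  expect_equal(org3$dm_demand, org$dm_demand * 3, tolerance = 1e-12)
})

test_that("leaf activity is interpolated and clipped to its printed range", {
  sp <- species_params(leaf_activity_table = data.frame(
    gdd = c(0, 1000, 2000), activity = c(5e-3, 1e-3, -1)))
  expect_equal(leaf_activity(0, sp), 1.9e-3)     # clipped above
  expect_equal(leaf_activity(2000, sp), 0)       # clipped below
  expect_equal(leaf_activity(1000, sp), 1e-3)
  expect_equal(leaf_activity(1500, sp), 0)       # interpolated then clipped
})

test_that("respiration obeys the Q10 law and the growth coefficient", {
  org <- data.frame(vertex = c("a", "b"), organ = c("fruit", "wood"),
                    dry_mass = c(0.008, 0.2), dm_demand_dm = c(1, 2),
                    dm_demand = c(0.5, 1), stringsAsFactors = FALSE)
  # null respiration: total demand reduces to the dry-matter demand
  r0 <- respiration_demand(org, 20, sp0)
  expect_equal(r0$total_demand, org$dm_demand)
  sp <- species_params(maintenance_coeff = c(fruit = 1e-4, wood = 2e-5),
                       growth_resp_coeff = 0.2, q10 = 2, tref_c = 20)
  # at the reference temperature the Q10 factor is exactly 1
  r1 <- respiration_demand(org, 20, sp)
  expect_equal(r1$resp_maint, org$dry_mass * 1000 * c(1e-4, 2e-5))
  expect_equal(r1$resp_growth, 0.2 * (r1$resp_maint + org$dm_demand))
  expect_equal(r1$total_demand,
               org$dm_demand * 1.2 + r1$resp_maint * 1.2)
  # doubling the mass doubles maintenance
  org2 <- org; org2$dry_mass <- org2$dry_mass * 2
  r2 <- respiration_demand(org2, 20, sp)
  expect_equal(r2$resp_maint, 2 * r1$resp_maint)
  # Q10: +10 C doubles the factor
  r3 <- respiration_demand(org, 30, sp)
  expect_equal(r3$resp_maint, 2 * r1$resp_maint)
  expect_error(respiration_demand(org, numeric(0), sp), "temperature")
})

test_that("supplies attach per leaf metamer, clip negatives and check ids", {
  tree <- chain_tree(10)
  tree$props[sprintf("c%02d", 1:10), "leaf_area"] <- 0.003
  tab <- data.frame(vertex_id = sprintf("c%02d", 1:10), gC_per_day = 0.1)
  s <- load_supply(tree, tab)
  expect_equal(sum(s), 1.0)
  expect_equal(unname(s[["ROOT0"]]), 0)
  # empty table: all-zero supply
  s0 <- load_supply(tree, tab[0, ])
  expect_equal(sum(s0), 0)
  # negatives clipped with a message
  tab$gC_per_day[3] <- -0.5
  expect_message(s2 <- load_supply(tree, tab), "clipped")
  expect_equal(sum(s2), 0.9)
  tab$vertex_id[1] <- "nope"
  expect_error(load_supply(tree, tab), "unknown leaf")
})

test_that("degree days accumulate above the 4.5 C base, floored at zero", {
  expect_equal(gdd_accumulate(c(10, 4, 14.5)), c(5.5, 5.5, 15.5))
})
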