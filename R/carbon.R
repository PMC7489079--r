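#' Species parameters for carbon demand and biomass allometry
#'
#' Bundles the allometric constants used to initialize biomasses, the
#' Gompertz sink-activity coefficients per organ type, the old-wood and
#' leaf activities, and the respiration configuration.  Defaults are the
#' apple ('Fuji') parameterization; respiration defaults are QualiTree-style
#' placeholders and should be set explicitly for quantitative work.
#'
#' Units: `wood_density` kg m^-3; `spec_leaf_surface` kg dry mass m^-2;
#' activities g g^-1 (degree-day)^-1; `dry_mass_to_C_mass` g dry mass per
#' g carbon; maintenance coefficients g C (g dry mass)^-1 day^-1.
#'
#' The shoot generalized linear model estimates whole-shoot dry weight (g)
#' from shoot length (cm) and cumulated thermal time GDD (degree-days):
#' `exp(a + b*log(L) + c*GDD + d*L + e*log(L*GDD))`.
#'
#' @param dry_mass_to_C_mass ratio converting assimilated carbon to dry
#'   biomass.
#' @param wood_density old-wood density.
#' @param spec_leaf_surface leaf dry mass per unit leaf surface.
#' @param dry_to_fresh_ratio apple fruit dry:fresh weight ratio.
#' @param shoot_to_root_growth vegetative shoot to root biomass ratio.
#' @param shoot_glm coefficients `a,b,c,d,e` of the shoot dry-weight model.
#' @param gompertz list of `c(a, b, c)` per organ type (`fruit`, `shoot`);
#'   sink activity is the normalized Gompertz derivative.
#' @param trunk_activity constant sink activity of old wood.
#' @param leaf_activity_table data.frame `gdd`, `activity` looked up (with
#'   linear interpolation) for leaf sink activity; values are clipped to
#'   `leaf_activity_range`.
#' @param leaf_activity_range admissible leaf-activity interval.
#' @param gdd_base_temp base temperature for growing degree days.
#' @param q10,tref_c Q10 coefficient and reference temperature of
#'   maintenance respiration.
#' @param maintenance_coeff named per-organ maintenance coefficients.
#' @param growth_resp_coeff growth respiration coefficient.
#' @param initial_fruit_mass_g initial fruit dry weight.
#' @return an object of class `species_params`.
#' @export
species_params <- function(
    dry_mass_to_C_mass = 2.105263158,
    wood_density = 700,
    spec_leaf_surface = 0.08,
    dry_to_fresh_ratio = 0.15,
    shoot_to_root_growth = 4.5,
    shoot_glm = c(a = -3.073409537, b = 0.706724497, c = 5.78e-05,
                  d = 0.020013707, e = 9.81e-05),
    gompertz = list(fruit = c(a = 63.703, b = -4.896, c = -0.00104),
                    shoot = c(a = 2.406, b = -2.84, c = -0.00165)),
    trunk_activity = 3.1e-05,
    leaf_activity_table = data.frame(gdd = c(0, 3000), activity = c(1e-3, 1e-3)),
    leaf_activity_range = c(0, 1.9e-3),
    gdd_base_temp = 4.5,
    q10 = 2.0,
    tref_c = 20,
    maintenance_coeff = c(wood = 0, internode = 0, leaf = 0, fruit = 0, root = 0),
    growth_resp_coeff = 0,
    initial_fruit_mass_g = 8) {
  p <- list(
    dry_mass_to_C_mass = dry_mass_to_C_mass, wood_density = wood_density,
    spec_leaf_surface = spec_leaf_surface,
    dry_to_fresh_ratio = dry_to_fresh_ratio,
    shoot_to_root_growth = shoot_to_root_growth, shoot_glm = shoot_glm,
    gompertz = gompertz, trunk_activity = trunk_activity,
    leaf_activity_table = leaf_activity_table,
    leaf_activity_range = leaf_activity_range,
    gdd_base_temp = gdd_base_temp, q10 = q10, tref_c = tref_c,
    maintenance_coeff = maintenance_coeff,
    growth_resp_coeff = growth_resp_coeff,
    initial_fruit_mass_g = initial_fruit_mass_g
  )
  class(p) <- "species_params"
  p
}

#' Growing degree days from daily mean temperatures
#'
#' Accumulates daily mean temperature above the species base temperature,
#' floored at zero.
#'
#' @param tmean_c vector of daily mean temperatures (deg C).
#' @param base_temp base temperature (deg C).
#' @return cumulated degree-days (last element = total).
#' @export
gdd_accumulate <- function(tmean_c, base_temp = 4.5) {
  cumsum(pmax(tmean_c - base_temp, 0))
}

#' Normalized Gompertz derivative (organ sink activity)
#'
#' For a Gompertz potential-growth curve `W(GDD) = a*exp(b*exp(c*GDD))`,
#' the relative growth rate
#' `(a*b*c*exp(b*exp(c*GDD) + c*GDD)) / (a*exp(b*exp(c*GDD)))`, which
#' simplifies algebraically to `b*c*exp(c*GDD)`.  The ratio form is
#' evaluated as printed; tests assert agreement with the simplification.
#'
#' @param gdd cumulated growing degree days (>= 0).
#' @param organ_params numeric `c(a, b, c)`; `b` and `c` are negative so
#'   the activity is positive and declines with thermal time.
#' @return activity in g g^-1 (degree-day)^-1.
#' @export
gompertz_rgr <- function(gdd, organ_params) {
  a <- organ_params[["a"]]; b <- organ_params[["b"]]; c <- organ_params[["c"]]
  (a * b * c * exp(b * exp(c * gdd) + c * gdd)) / (a * exp(b * exp(c * gdd)))
}

#' Leaf sink activity from the lookup table
#'
#' Linear interpolation in the species leaf-activity table (flat beyond the
#' table range), clipped to the admissible range.
#'
#' @param gdd cumulated growing degree days.
#' @param params a [species_params()] object.
#' @return activity in g g^-1 (degree-day)^-1.
#' @export
leaf_activity <- function(gdd, params) {
  tb <- params$leaf_activity_table
  act <- stats::approx(tb$gdd, tb$activity, xout = gdd, rule = 2)$y
  pmin(pmax(act, params$leaf_activity_range[1]), params$leaf_activity_range[2])
}

#' Initialize organ biomasses from allometry
#'
#' Converts the geometric description of the tree into dry masses, one
#' organ row per (metamer, organ):
#' \itemize{
#'   \item old wood (and current-year internodes of woody age classes):
#'     cylinder volume x wood density;
#'   \item current-year shoot stems: whole-shoot dry weight from the shoot
#'     GLM on total shoot length (cm) and GDD, distributed over the
#'     shoot's metamers proportionally to metamer length;
#'   \item leaves: `leaf_area x spec_leaf_surface`;
#'   \item fruits: the initial fruit dry weight (8 g);
#'   \item root compartment: one `root` organ of zero initial mass (its
#'     demand is ratio-driven, not mass-driven).
#' }
#'
#' @param tree a `mst` object with lengths, radii, leaf areas and years.
#' @param params a [species_params()] object.
#' @param gdd_cum cumulated growing degree days used by the shoot GLM.
#' @return `tree` with an `organs` data.frame (`vertex`, `organ`,
#'   `dry_mass` in kg) attached.
#' @export
init_biomass <- function(tree, params = species_params(), gdd_cum = 500) {
  vs <- vertices_at(tree, finest_scale(tree))
  ot <- tree$props[vs, "organ_type"]
  year <- tree$props[vs, "year"]
  len <- tree$props[vs, "length"]
  rad <- tree$props[vs, "radius"]
  la <- tree$props[vs, "leaf_area"]
  fruit <- tree$props[vs, "has_fruit"]
  cy <- suppressWarnings(max(year, na.rm = TRUE))

  rows <- list()
  add <- function(v, organ, kg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      vertex = v, organ = organ, dry_mass = kg, stringsAsFactors = FALSE)
  }

  is_root <- ot == "root_compartment"
  is_shoot <- !is_root & !is.na(year) & year == cy
  is_wood <- !is_root & !is_shoot

  for (v in vs[is_wood]) {
    kg <- pi * tree$props[v, "radius"]^2 * tree$props[v, "length"] *
      params$wood_density
    add(v, "wood", kg)
  }

  # whole current-year shoots: GLM mass split over metamers by length
  if (any(is_shoot)) {
    sub <- .current_year_subtrees(tree)
    sub <- sub[vs[is_shoot]]
    for (b in unique(sub)) {
      members <- names(sub)[sub == b]
      L_cm <- sum(tree$props[members, "length"]) * 100
      if (L_cm <= 0) {
        stop("current-year shoot at '", b, "' has nonpositive length")
      }
      g <- shoot_dry_weight(L_cm, gdd_cum, params)
      w <- tree$props[members, "length"]
      for (k in seq_along(members)) {
        add(members[k], "internode", g / 1000 * w[k] / sum(w))
      }
    }
  }

  for (v in vs[!is_root & !is.na(la) & la > 0]) {
    add(v, "leaf", tree$props[v, "leaf_area"] * params$spec_leaf_surface)
  }
  for (v in vs[!is_root & !is.na(fruit) & fruit > 0]) {
    add(v, "fruit", params$initial_fruit_mass_g / 1000)
  }
  add(vs[is_root], "root", 0)

  organs <- do.call(rbind, rows)
  organs <- organs[order(organs$vertex, organs$organ), ]
  rownames(organs) <- NULL
  tree$organs <- organs
  tree
}

#' Shoot dry weight from the length/thermal-time allometry
#'
#' `exp(a + b*log(L) + c*GDD + d*L + e*log(L*GDD))` with shoot length `L`
#' in cm and `GDD` in degree-days; returns grams.
#'
#' @param length_cm shoot length in cm (> 0).
#' @param gdd_cum cumulated growing degree days (> 0).
#' @param params a [species_params()] object.
#' @return dry weight in g.
#' @export
shoot_dry_weight <- function(length_cm, gdd_cum, params = species_params()) {
  if (any(length_cm <= 0)) stop("shoot length must be positive")
  g <- params$shoot_glm
  exp(g[["a"]] + g[["b"]] * log(length_cm) + g[["c"]] * gdd_cum +
        g[["d"]] * length_cm + g[["e"]] * log(length_cm * gdd_cum))
}

#' Daily dry-matter carbon demand per organ
#'
#' Demand for dry-matter accumulation of organ `j` on one day:
#' `dry weight x sink activity(GDD, organ type) x GDD of the day`,
#' converted from dry mass to carbon with the species dry-mass:carbon
#' ratio.  Activities: fruits and shoot stems use the normalized Gompertz
#' derivative of their organ type; old wood uses the constant old-wood
#' activity; leaves use the lookup table; the root's demand is the total
#' vegetative shoot (stem + leaf) demand divided by the shoot:root growth
#' ratio.
#'
#' @param tree a `mst` with biomass initialized ([init_biomass()]).
#' @param params a [species_params()] object.
#' @param gdd_cum cumulated growing degree days at the simulated day.
#' @param gdd_day degree-days of the simulated day.
#' @return the `organs` data.frame with columns `activity`
#'   (g g^-1 dd^-1), `dm_demand_dm` (g dry mass) and `dm_demand` (g C).
#' @export
organ_demand <- function(tree, params = species_params(), gdd_cum, gdd_day) {
  org <- tree$organs
  if (is.null(org)) stop("tree has no organ biomasses; run init_biomass()")
  act <- numeric(nrow(org))
  for (k in seq_len(nrow(org))) {
    act[k] <- switch(org$organ[k],
      fruit = gompertz_rgr(gdd_cum, params$gompertz$fruit),
      internode = gompertz_rgr(gdd_cum, params$gompertz$shoot),
      wood = params$trunk_activity,
      leaf = leaf_activity(gdd_cum, params),
      root = 0,
      stop("unknown organ type: ", org$organ[k]))
  }
  org$activity <- act
  org$dm_demand_dm <- org$dry_mass * 1000 * act * gdd_day
  veg <- org$organ %in% c("internode", "leaf")
  org$dm_demand_dm[org$organ == "root"] <-
    sum(org$dm_demand_dm[veg]) / params$shoot_to_root_growth
  org$dm_demand <- org$dm_demand_dm / params$dry_mass_to_C_mass
  org
}

#' Daily respiration demand per organ
#'
#' Maintenance respiration is proportional to dry mass through a per-organ
#' maintenance coefficient and a Q10 temperature response, averaged over
#' the day's temperature record; growth respiration is the growth
#' respiration coefficient times the sum of maintenance respiration and
#' the dry-matter carbon demand.  The total carbon demand of an organ is
#' dry-matter demand + maintenance + growth respiration.
#'
#' @param organs output of [organ_demand()].
#' @param temperature_c vector of within-day temperatures (deg C); its
#'   mean Q10 factor drives maintenance.
#' @param params a [species_params()] object.
#' @return `organs` with columns `resp_maint`, `resp_growth` (g C) and
#'   `total_demand` (g C).
#' @export
respiration_demand <- function(organs, temperature_c, params = species_params()) {
  if (length(temperature_c) < 1L) stop("missing temperature series")
  q10f <- mean(params$q10^((temperature_c - params$tref_c) / 10))
  mr <- params$maintenance_coeff[organs$organ]
  mr[is.na(mr)] <- 0
  organs$resp_maint <- organs$dry_mass * 1000 * unname(mr) * q10f
  organs$resp_growth <- params$growth_resp_coeff *
    (organs$resp_maint + organs$dm_demand)
  organs$total_demand <- organs$dm_demand + organs$resp_maint +
    organs$resp_growth
  organs
}

#' Attach per-leaf carbon supplies to the tree's metamers
#'
#' Supplies are given per leaf-bearing metamer in g C per day (a pluggable
#' replacement for a radiative/photosynthesis model).  Negative net values
#' are clipped to zero and the clipped total reported in a message.
#'
#' @param tree a `mst` object.
#' @param supply_table data.frame `vertex_id`, `gC_per_day`.
#' @return named numeric vector of g C/day over all metamers (zero where
#'   no supply).
#' @export
load_supply <- function(tree, supply_table) {
  vs <- vertices_at(tree, finest_scale(tree))
  bad <- setdiff(supply_table$vertex_id, vs)
  if (length(bad)) {
    stop("supply table references unknown leaf vertices: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  supply <- stats::setNames(rep(0, length(vs)), vs)
  val <- supply_table$gC_per_day
  neg <- val < 0
  if (any(neg)) {
    message("clipped ", sum(neg), " negative supplies totalling ",
            signif(sum(val[neg]), 4), " g C to zero")
    val[neg] <- 0
  }
  supply[supply_table$vertex_id] <- supply[supply_table$vertex_id] + val
  supply
}
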