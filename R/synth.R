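#' Configuration for the synthetic apple-like tree generator
#'
#' The generator emulates the architecture the model is applied to: a
#' vertical trunk of growth units (one per year of age), first-order
#' branches borne on the older trunk growth units, one-year-old wood
#' sections bearing current-year leafy shoots, leaves on current-year
#' metamers and fruits on a fraction of the shoots.  All stochastic
#' features draw from fixed-offset substreams of one seed, so the same
#' seed always yields the identical tree.
#'
#' @param seed integer seed.
#' @param n_trunk_gus number of trunk growth units (= tree age in years).
#' @param metamers_per_gu metamers per woody growth unit.
#' @param branch_lambda Poisson mean of branches per old trunk growth
#'   unit.
#' @param shoots_per_unit lateral current-year shoots per one-year-old
#'   growth unit (a terminal extension shoot is always added).
#' @param shoot_length_cm_mean,shoot_length_cm_sd normal distribution of
#'   shoot length (cm), truncated at one metamer.
#' @param metamer_length_m metamer (internode) length in metres.
#' @param leaf_area_m2 leaf area per leafy metamer (m^2).
#' @param fruit_probability probability that a shoot bears one fruit (on
#'   its basal metamer).
#' @param trunk_radius_m trunk base radius; branch radii taper with age.
#' @param branch_angle_deg mean insertion angle of branches from
#'   vertical.
#' @param max_assim_gC_m2 maximal leaf assimilation for the light stub
#'   (g C m^-2 day^-1).
#' @param extinction_k canopy light-extinction coefficient (m^-1) for the
#'   supply stub.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_trunk_gus = 4, metamers_per_gu = 8,
                         branch_lambda = 3, shoots_per_unit = 2,
                         shoot_length_cm_mean = 16, shoot_length_cm_sd = 4,
                         metamer_length_m = 0.02, leaf_area_m2 = 0.003,
                         fruit_probability = 0.6, trunk_radius_m = 0.025,
                         branch_angle_deg = 50, max_assim_gC_m2 = 6,
                         extinction_k = 0.5) {
  stopifnot(fruit_probability >= 0, fruit_probability <= 1,
            metamer_length_m > 0, n_trunk_gus >= 1, metamers_per_gu >= 1)
  structure(as.list(environment()), class = "synth_config")
}

# run `expr` under a fixed seed without touching the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic apple-like multi-scale tree
#'
#' Builds a base two-scale tree (plant, metamer) with per-metamer organ
#' type, year, growth-unit label, 3-D coordinates, radius, length and
#' leaf area, from which all five working scales (M, GU, TBS, BR1, FU)
#' can be built.  Deterministic per seed.
#'
#' @param config a [synth_config()].
#' @return a validated `mst`.
#' @export
generate_tree <- function(config = synth_config()) {
  cf <- config
  cy <- cf$n_trunk_gus                      # current year index
  old_gus <- seq_len(max(cy - 1, 0))
  n_br <- if (length(old_gus)) {
    .with_seed(cf$seed + 1L, stats::rpois(length(old_gus), cf$branch_lambda))
  } else integer(0)

  # every one-year-old growth unit bears `shoots_per_unit` laterals plus a
  # terminal extension; count shoots up-front for the length substream
  n_units_1yo <- sum(n_br) * 0 + 0
  # branches on trunk GU year y carry wood GUs years (y+1)..(cy-1); the
  # terminal one (year cy-1) bears shoots. A branch on GU cy-1 is itself a
  # current-year shoot.
  br_on <- rep(old_gus, n_br)
  br_has_wood <- br_on < cy - 1
  n_units_1yo <- sum(br_has_wood) + (cy > 1)   # branch terminals + trunk GU cy-1
  n_shoots <- n_units_1yo * (cf$shoots_per_unit + 1L) + sum(!br_has_wood) +
    (cy == 1)
  shoot_len <- .with_seed(cf$seed + 2L,
    pmax(stats::rnorm(max(n_shoots, 1), cf$shoot_length_cm_mean,
                      cf$shoot_length_cm_sd), 100 * cf$metamer_length_m))
  fruit_flag <- .with_seed(cf$seed + 3L,
    stats::runif(max(n_shoots, 1)) < cf$fruit_probability)
  n_angles <- length(br_on) + n_shoots
  angles <- .with_seed(cf$seed + 4L, list(
    az = stats::runif(max(n_angles, 1), 0, 2 * pi),
    el = stats::rnorm(max(n_angles, 1), cf$branch_angle_deg, 8) * pi / 180))

  rows <- list()
  nid <- 0L
  shoot_i <- 0L
  angle_i <- 0L
  new_id <- function() {
    nid <<- nid + 1L
    sprintf("v%05d", nid)
  }
  add_row <- function(id, parent, edge, organ, year, top, radius, len,
                      la, fruit, gu) {
    rows[[length(rows) + 1L]] <<- data.frame(
      vertex_id = id, parent_id = parent, edge_type = edge,
      organ_type = organ, year = year,
      top_x = top[1], top_y = top[2], top_z = top[3],
      radius = radius, length = len, leaf_area = la, has_fruit = fruit,
      gu = gu, stringsAsFactors = FALSE)
  }
  # grow a straight axis of n metamers; returns ids and tops
  grow_axis <- function(n, parent, edge, base, dir, organ, year, radius,
                        len, la, gu, fruit_on_first = FALSE) {
    ids <- character(n)
    tops <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      id <- new_id()
      top <- base + k * len * dir
      add_row(id, parent, if (k == 1) edge else "<", organ, year, top,
              radius, len, la, as.numeric(fruit_on_first && k == 1), gu)
      ids[k] <- id
      tops[k, ] <- top
      parent <- id
    }
    list(ids = ids, tops = tops, tip = parent,
         tip_top = base + n * len * dir)
  }
  dir_from <- function() {
    angle_i <<- angle_i + 1L
    el <- angles$el[angle_i]
    az <- angles$az[angle_i]
    c(sin(el) * cos(az), sin(el) * sin(az), cos(el))
  }
  next_shoot <- function(parent, edge, base, year, gu) {
    shoot_i <<- shoot_i + 1L
    L <- shoot_len[shoot_i]
    n <- max(1L, round(L / 100 / cf$metamer_length_m))
    grow_axis(n, parent, edge, base, dir_from(), "internode", year,
              0.003, cf$metamer_length_m, cf$leaf_area_m2, gu,
              fruit_on_first = fruit_flag[shoot_i])
  }

  gu_n <- 0L
  new_gu <- function() {
    gu_n <<- gu_n + 1L
    sprintf("gu%04d", gu_n)
  }

  # trunk: woody GUs years 1..cy-1, leafy extension year cy
  trunk_tip <- NA_character_
  trunk_base <- c(0, 0, 0)
  gu_tips <- list()   # per old trunk GU: tip id/top for branch insertion
  gu_mets <- list()
  for (g in seq_len(cy)) {
    if (g < cy) {
      rad <- cf$trunk_radius_m * sqrt((cy - g + 1) / cy)
      ax <- grow_axis(cf$metamers_per_gu,
                      trunk_tip, "<", trunk_base, c(0, 0, 1),
                      "wood", g, rad, cf$metamer_length_m * 1.5, 0,
                      new_gu())
      gu_tips[[g]] <- ax
      gu_mets[[g]] <- ax$ids
      trunk_tip <- ax$tip
      trunk_base <- ax$tip_top
    } else {
      ax <- next_shoot(trunk_tip, "<", trunk_base, cy, new_gu())
      trunk_tip <- ax$tip
    }
  }
  if (cy > 1) {
    # lateral shoots on the one-year-old trunk GU
    host <- gu_tips[[cy - 1]]
    for (ssk in seq_len(cf$shoots_per_unit)) {
      at <- 1 + (ssk - 1) %% cf$metamers_per_gu
      next_shoot(host$ids[at], "+", host$tops[at, ], cy, new_gu())
    }
  }
  # branches
  for (bi in seq_along(br_on)) {
    y <- br_on[bi]
    host <- gu_tips[[y]]
    at <- 1 + (bi - 1) %% cf$metamers_per_gu
    par <- host$ids[at]
    base <- host$tops[at, ]
    if (!br_has_wood[bi]) {
      next_shoot(par, "+", base, cy, new_gu())
      next
    }
    dir <- dir_from()
    edge <- "+"
    last <- NULL
    for (y2 in (y + 1):(cy - 1)) {
      rad <- cf$trunk_radius_m * 0.4 * sqrt((cy - y2 + 1) / cy)
      ax <- grow_axis(cf$metamers_per_gu, par, edge, base, dir, "wood",
                      y2, rad, cf$metamer_length_m, 0, new_gu())
      par <- ax$tip
      base <- ax$tip_top
      edge <- "<"
      last <- ax
    }
    # the terminal (one-year-old) branch GU bears shoots
    for (ssk in seq_len(cf$shoots_per_unit)) {
      at <- 1 + (ssk - 1) %% cf$metamers_per_gu
      next_shoot(last$ids[at], "+", last$tops[at, ], cy, new_gu())
    }
    next_shoot(par, "<", base, cy, new_gu())
  }

  df <- do.call(rbind, rows)
  df$parent_id[is.na(df$parent_id)] <- NA_character_
  mst_from_table(df, unit = "m")
}

#' Generate per-leaf carbon supplies with an exponential light stub
#'
#' A toy replacement for a radiative/photosynthesis model: each
#' leaf-bearing metamer receives
#' `leaf_area x max_assim x exp(-k x depth)` g C per day, where depth is
#' the vertical distance below the highest leaf.  Deterministic given the
#' tree and config.
#'
#' @param tree a `mst` object.
#' @param config a [synth_config()] (fields `max_assim_gC_m2`,
#'   `extinction_k`).
#' @return data.frame `vertex_id`, `gC_per_day` for [load_supply()].
#' @export
generate_supply <- function(tree, config = synth_config()) {
  vs <- vertices_at(tree, finest_scale(tree))
  la <- tree$props[vs, "leaf_area"]
  leafy <- vs[!is.na(la) & la > 0]
  if (!length(leafy)) stop("tree has no leaves")
  z <- tree$props[leafy, "top_z"]
  depth <- max(z) - z
  data.frame(
    vertex_id = leafy,
    gC_per_day = tree$props[leafy, "leaf_area"] * config$max_assim_gC_m2 *
      exp(-config$extinction_k * depth),
    stringsAsFactors = FALSE)
}
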