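#' Assemble the metamer-scale carbon state
#'
#' Combines organ demands and per-leaf supplies into the per-metamer state
#' used by the allocation step.
#'
#' @param tree a `mst` with biomass initialized.
#' @param organs output of [respiration_demand()] (or [organ_demand()],
#'   in which case respiration terms are taken as zero).
#' @param supply named supply vector from [load_supply()] (g C/day).
#' @param reserve optional named per-metamer reserve pool (g C) carried
#'   over from the previous day; it is re-offered as supply.
#' @return a data.frame (one row per metamer) with columns `vertex`,
#'   `dm_demand`, `resp_demand`, `demand` (total, g C), `supply` (g C).
#' @export
carbon_state <- function(tree, organs, supply, reserve = NULL) {
  vs <- vertices_at(tree, finest_scale(tree))
  if (is.null(organs$total_demand)) {
    organs$resp_maint <- 0
    organs$resp_growth <- 0
    organs$total_demand <- organs$dm_demand
  }
  dm <- tapply(organs$dm_demand, organs$vertex, sum)
  tot <- tapply(organs$total_demand, organs$vertex, sum)
  st <- data.frame(vertex = vs,
                   dm_demand = 0, resp_demand = 0, demand = 0,
                   supply = 0, stringsAsFactors = FALSE)
  rownames(st) <- vs
  st[names(dm), "dm_demand"] <- dm
  st[names(tot), "demand"] <- tot
  st$resp_demand <- st$demand - st$dm_demand
  st[names(supply), "supply"] <- st[names(supply), "supply"] + unname(supply)
  if (!is.null(reserve)) {
    st[names(reserve), "supply"] <- st[names(reserve), "supply"] +
      unname(reserve)
  }
  st
}

#' Up-scale a carbon state to a coarse scale
#'
#' Demand and supply of a coarse component are the sums over its
#' components, so totals are conserved exactly across scales.
#'
#' @param tree a `mst` carrying the built scale.
#' @param state metamer-scale state from [carbon_state()].
#' @param scale_name the coarse scale (or `"M"` for the identity).
#' @return state data.frame at the coarse scale.
#' @export
upscale_state <- function(tree, state, scale_name) {
  s <- scale_index(tree, scale_name)
  if (s == finest_scale(tree)) return(state)
  if (s == 1L) stop("cannot allocate at the plant scale")
  cx <- tree$complex[state$vertex]
  agg <- function(x) tapply(x, cx, sum)
  up <- data.frame(
    vertex = sort(unique(cx)),
    stringsAsFactors = FALSE
  )
  rownames(up) <- up$vertex
  for (cc in c("dm_demand", "resp_demand", "demand", "supply")) {
    a <- agg(state[[cc]])
    up[[cc]] <- as.numeric(a[up$vertex])
  }
  up
}

#' Source-sink carbon allocation at one scale
#'
#' Each source `i` distributes its available carbon `ACP_i` over the sinks
#' in proportion to sink demand weighted by the distance kernel
#' `f(d, h) = 1/(1+d)^h`:
#' `F_ij = Demand_j f(d_ij, h) ACP_i / sum_k Demand_k f(d_ik, h)`.
#' Per-sink totals above the sink's demand are stored in the component's
#' reserve pool (no redistribution within the time step).  With `h = 0`
#' the kernel is distance-free and the model reduces to a common
#' assimilate pool.
#'
#' Weights are computed in log space so very large `h` (nearest-sink
#' limit) stays numerically stable.
#'
#' @param distances distance matrix from [distance_matrix()] covering all
#'   components with positive supply (rows) and demand (columns).
#' @param state component state at the working scale ([carbon_state()] or
#'   [upscale_state()]).
#' @param h friction parameter (>= 0).
#' @return a list with `flows` (source x sink matrix, g C), `received`
#'   (per-sink total, g C), `growth_alloc` (min(received, demand)),
#'   `reserve` (excess, g C), all named by component.
#' @export
allocate <- function(distances, state, h) {
  stopifnot(h >= 0, is.finite(h))
  sources <- state$vertex[state$supply > 0]
  sinks <- state$vertex[state$demand > 0]
  received <- stats::setNames(rep(0, nrow(state)), state$vertex)
  flows <- matrix(0, length(sources), length(sinks),
                  dimnames = list(sources, sinks))
  if (length(sources) && !length(sinks)) {
    warning("positive supply but all demands zero: everything to reserves")
  }
  if (length(sources) && length(sinks)) {
    D <- distances[sources, sinks, drop = FALSE]
    logw <- -h * log1p(D)
    logw <- sweep(logw, 2, log(state[sinks, "demand"]), "+")
    mx <- apply(logw, 1, max)
    W <- exp(logw - mx)
    W <- W / rowSums(W)
    flows <- W * state[sources, "supply"]
    received[sinks] <- colSums(flows)
  }
  demand <- stats::setNames(state$demand, state$vertex)
  growth <- pmin(received, demand)
  reserve <- received - growth
  # components with supply but no sink anywhere keep their carbon
  if (!length(sinks)) reserve[sources] <- reserve[sources] +
      state[sources, "supply"]
  list(flows = flows, received = received, growth_alloc = growth,
       reserve = reserve)
}

#' Down-scale a coarse allocation to metamers and organs
#'
#' The carbon allocated to a coarse component is divided among its
#' metamers, and within each metamer among its organs, proportionally to
#' their individual total carbon demands.  A component receiving carbon
#' while having zero demand routes it to its reserve.
#'
#' @param tree a `mst` carrying the working scale.
#' @param alloc result of [allocate()] at the working scale.
#' @param state metamer-scale state ([carbon_state()]).
#' @param organs organ table with `total_demand` ([respiration_demand()]).
#' @param scale_name the working scale.
#' @return a list with `metamer_alloc` (named g C per metamer, growth
#'   part), `organ_alloc` (organ table with column `allocated`, g C) and
#'   `reserve` (named per-metamer reserve additions, g C; coarse reserves
#'   are booked on the component's base metamer).
#' @export
downscale_allocation <- function(tree, alloc, state, organs, scale_name) {
  s <- scale_index(tree, scale_name)
  vs <- state$vertex
  met_growth <- stats::setNames(rep(0, length(vs)), vs)
  met_res <- stats::setNames(rep(0, length(vs)), vs)
  if (s == finest_scale(tree)) {
    met_growth[names(alloc$growth_alloc)] <- alloc$growth_alloc
    met_res[names(alloc$reserve)] <- alloc$reserve
  } else {
    dem <- stats::setNames(state$demand, vs)
    cx <- tree$complex[vs]
    for (I in names(alloc$growth_alloc)) {
      a <- alloc$growth_alloc[[I]]
      r <- alloc$reserve[[I]]
      members <- vs[cx == I]
      dtot <- sum(dem[members])
      base <- members[is.na(tree$parent[members]) |
                        !(tree$parent[members] %in% members)]
      if (a > 0) {
        if (dtot > 0) {
          met_growth[members] <- met_growth[members] + a * dem[members] / dtot
        } else {
          warning("component '", I, "' received carbon with zero demand; ",
                  "routed to reserve")
          r <- r + a
        }
      }
      if (r > 0) met_res[base] <- met_res[base] + r
    }
  }
  # within-metamer split over organs by total demand
  organs$allocated <- 0
  otot <- tapply(organs$total_demand, organs$vertex, sum)
  for (v in vs[met_growth[vs] > 0]) {
    idx <- which(organs$vertex == v)
    dt <- otot[[v]]
    if (is.null(dt) || is.na(dt) || dt <= 0) {
      met_res[v] <- met_res[v] + met_growth[[v]]
      met_growth[v] <- 0
      next
    }
    organs$allocated[idx] <- met_growth[[v]] *
      organs$total_demand[idx] / dt
  }
  list(metamer_alloc = met_growth, organ_alloc = organs, reserve = met_res)
}

#' Update organ dry masses from an allocation
#'
#' The carbon allocated to an organ covers dry-matter accumulation and
#' respiration in proportion to their shares of the organ's total demand;
#' the dry-matter share is converted to a dry-mass increment with the
#' species dry-mass:carbon ratio.
#'
#' @param tree a `mst` with organ biomasses.
#' @param organ_alloc organ table with `allocated` from
#'   [downscale_allocation()].
#' @param params a [species_params()] object.
#' @return a list with `tree` (organ masses incremented) and `organs`
#'   (the table with column `dm_increment`, g dry mass).
#' @export
update_masses <- function(tree, organ_alloc, params = species_params()) {
  org <- organ_alloc
  share <- ifelse(org$total_demand > 0,
                  org$dm_demand / org$total_demand, 0)
  org$dm_increment <- org$allocated * share * params$dry_mass_to_C_mass
  key <- paste(tree$organs$vertex, tree$organs$organ)
  inc <- stats::setNames(org$dm_increment, paste(org$vertex, org$organ))
  tree$organs$dry_mass <- tree$organs$dry_mass +
    ifelse(is.na(inc[key]), 0, inc[key]) / 1000
  list(tree = tree, organs = org)
}

#' Run one day of carbon allocation at a chosen scale
#'
#' Orchestrates the full daily step: organ demands (dry matter +
#' respiration) at the metamer scale, state assembly with supplies and
#' carried-over reserves, up-scaling to the working scale, geometry and
#' distance computation, source-sink allocation, down-scaling to organs,
#' and dry-mass update.
#'
#' @param tree a `mst` with biomass initialized and, for coarse runs, the
#'   working scale built ([build_scale()]).
#' @param supply named per-metamer supply vector (g C/day), e.g. from
#'   [load_supply()] or [generate_supply()].
#' @param params a [species_params()] object.
#' @param scale_name working scale (default the metamer scale).
#' @param h friction parameter.
#' @param gdd_cum,gdd_day cumulated and daily growing degree days.
#' @param temperature_c within-day temperatures for maintenance
#'   respiration.
#' @param reserve optional named per-metamer reserve carried over.
#' @return a list of class `allocation_result`: `organs` (per-organ
#'   allocated g C and dm_increment g), `metamer_alloc`, `reserve`,
#'   `component_alloc` (per working-scale component growth allocation),
#'   `flows`, `state` (working-scale state), `tree` (updated), and the
#'   run configuration.
#' @export
run_day <- function(tree, supply, params = species_params(),
                    scale_name = "M", h = 8,
                    gdd_cum = 1000, gdd_day = 10,
                    temperature_c = 20, reserve = NULL) {
  org <- organ_demand(tree, params, gdd_cum, gdd_day)
  org <- respiration_demand(org, temperature_c, params)
  stM <- carbon_state(tree, org, supply, reserve)
  st <- upscale_state(tree, stM, scale_name)
  geom <- annotate_geometry(tree, scale_name)
  act <- st$vertex[st$supply > 0 | st$demand > 0]
  D <- distance_matrix(tree, geom, scale_name, sources = act, sinks = act)
  al <- allocate(D, st, h)
  down <- downscale_allocation(tree, al, stM, org, scale_name)
  up <- update_masses(tree, down$organ_alloc, params)
  structure(list(
    organs = up$organs,
    metamer_alloc = down$metamer_alloc,
    reserve = down$reserve,
    component_alloc = al$growth_alloc,
    flows = al$flows,
    state = st,
    state_metamer = stM,
    tree = up$tree,
    config = list(scale = tree$scale_names[scale_index(tree, scale_name)],
                  h = h, gdd_cum = gdd_cum, gdd_day = gdd_day)
  ), class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat("Carbon allocation result\n")
  cat(sprintf("  scale: %s, h = %g\n", x$config$scale, x$config$h))
  cat(sprintf("  total supply: %.4g g C, total demand: %.4g g C\n",
              sum(x$state$supply), sum(x$state$demand)))
  cat(sprintf("  growth-allocated: %.4g g C, to reserves: %.4g g C\n",
              sum(x$organs$allocated), sum(x$reserve)))
  fr <- x$organs$organ == "fruit"
  if (any(fr)) {
    cat(sprintf("  fruits: %d, mean dry-mass increment: %.4g g\n",
                sum(fr), mean(x$organs$dm_increment[fr])))
  }
  invisible(x)
}
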