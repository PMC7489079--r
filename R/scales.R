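#' Scale specifications
#'
#' A scale specification names a new topological scale and carries the
#' grouping rule that assigns every metamer to a group.  Groups must be
#' connected subtrees; the root compartment is always its own group.
#'
#' Built-in rules:
#' \describe{
#'   \item{`"M"`}{identity: each metamer its own group.}
#'   \item{`"GU"`}{growth units: group by the `gu` label property.}
#'   \item{`"TBS"`}{trunk, first-order branches and current-year leafy
#'     shoots (see [classify_tbs()]).}
#'   \item{`"BR1"`}{trunk plus each entire first-order branch subtree,
#'     shoots included (see [classify_br1()]).}
#'   \item{`"FU"`}{fruiting units: each maximal section of one-year-old
#'     wood together with the current-year shoots it bears (see
#'     [classify_fu()]).}
#'   \item{`"plant"`}{everything above ground in one group.}
#' }
#'
#' @param name scale name; one of the built-ins above or any other string
#'   when `rule` is supplied.
#' @param rule for custom scales, a `function(tree)` returning a character
#'   vector of group labels named by metamer-scale vertex id.
#' @return an object of class `scale_spec`.
#' @export
scale_spec <- function(name, rule = NULL) {
  builtin <- list(
    M   = function(tree) {
      vs <- vertices_at(tree, finest_scale(tree))
      stats::setNames(vs, vs)
    },
    GU  = .rule_gu,
    TBS = classify_tbs,
    BR1 = classify_br1,
    FU  = classify_fu,
    plant = function(tree) {
      vs <- vertices_at(tree, finest_scale(tree))
      stats::setNames(rep("plant", length(vs)), vs)
    }
  )
  if (is.null(rule)) {
    rule <- builtin[[name]]
    if (is.null(rule)) {
      stop("no built-in rule for scale '", name,
           "'; supply a grouping `rule` function")
    }
  }
  structure(list(name = name, rule = rule), class = "scale_spec")
}

.rule_gu <- function(tree) {
  vs <- vertices_at(tree, finest_scale(tree))
  gu <- tree$props[vs, "gu"]
  ot <- tree$props[vs, "organ_type"]
  miss <- vs[is.na(gu) & ot != "root_compartment"]
  if (length(miss)) {
    stop("metamer '", miss[1], "' has no growth-unit (gu) label")
  }
  stats::setNames(paste0("GU.", gu), vs)
}

#' Branching order of metamers
#'
#' Order 0 is the trunk axis; the order increments by one at every
#' branching (`"+"`) edge on the path from the root.  Succession (`"<"`)
#' edges keep the order.  This is the standard MTG convention.
#'
#' @param tree a `mst` object.
#' @return named integer vector over metamer-scale vertices.
#' @export
branching_order <- function(tree) {
  vs <- vertices_at(tree, finest_scale(tree))
  ord <- stats::setNames(rep(NA_integer_, length(vs)), vs)
  root <- vs[is.na(tree$parent[vs])]
  ord[root] <- 0L
  # children map
  has_par <- vs[!is.na(tree$parent[vs])]
  kids_of <- split(has_par, tree$parent[has_par])
  queue <- root
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (kid in kids_of[[cur]]) {
      ord[kid] <- ord[cur] + (tree$edge[[kid]] == "+")
      queue <- c(queue, kid)
    }
  }
  ord
}

# maximal connected current-year subtrees; returns named label vector over
# the current-year metamers (label = id of the subtree's base vertex)
.current_year_subtrees <- function(tree) {
  vs <- vertices_at(tree, finest_scale(tree))
  vs <- vs[tree$props[vs, "organ_type"] != "root_compartment"]
  year <- tree$props[vs, "year"]
  cy <- max(year, na.rm = TRUE)
  cur <- vs[!is.na(year) & year == cy]
  lab <- stats::setNames(rep(NA_character_, length(cur)), cur)
  for (v in cur) {        # ascending id; parents may come after children
    chain <- v
    w <- v
    repeat {
      p <- tree$parent[[w]]
      if (is.na(p) || !(p %in% cur)) break
      if (!is.na(lab[p])) { lab[chain] <- lab[p]; chain <- character(0); break }
      chain <- c(chain, p)
      w <- p
    }
    if (length(chain)) lab[chain] <- w   # w is the base of this subtree
  }
  lab
}

#' Classify metamers into trunk, branches and leafy shoots
#'
#' The trunk is the order-0 axis; each first-order branch is the woody part
#' of an order-1 subtree borne on the trunk; leafy shoots are maximal
#' current-year subtrees bearing at least one leaf.  Current-year subtrees
#' without leaves stay with their supporting wood.  The root compartment is
#' its own group.
#'
#' @param tree a `mst` object with `year` and `leaf_area` properties.
#' @return named character vector of group labels over metamers.
#' @export
classify_tbs <- function(tree) {
  vs <- vertices_at(tree, finest_scale(tree))
  ot <- tree$props[vs, "organ_type"]
  ord <- branching_order(tree)
  if (anyNA(ord[ot != "root_compartment"])) {
    stop("undefined branching order for metamer '",
         vs[which(is.na(ord) & ot != "root_compartment")[1]], "'")
  }
  lab <- stats::setNames(rep(NA_character_, length(vs)), vs)
  lab[ot == "root_compartment"] <- "root"

  sub <- .current_year_subtrees(tree)
  la <- tree$props[names(sub), "leaf_area"]
  leafy_base <- unique(sub[!is.na(la) & la > 0])
  is_shoot <- names(sub)[sub %in% leafy_base]
  lab[is_shoot] <- paste0("shoot.", sub[is_shoot])

  rest <- vs[is.na(lab)]
  lab[rest[ord[rest] == 0L]] <- "trunk"
  rest <- vs[is.na(lab)]
  if (length(rest)) {
    broot <- .branch_root(tree, vs, ord)
    lab[rest] <- paste0("branch.", broot[rest])
  }
  lab
}

# for every metamer of order >= 1: the order-1 ancestor attached to the
# trunk that heads its first-order branch subtree
.branch_root <- function(tree, vs, ord) {
  br <- stats::setNames(rep(NA_character_, length(vs)), vs)
  root <- vs[is.na(tree$parent[vs])]
  has_par <- vs[!is.na(tree$parent[vs])]
  kids_of <- split(has_par, tree$parent[has_par])
  queue <- root
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (kid in kids_of[[cur]]) {
      br[kid] <- if (ord[cur] == 0L && ord[kid] >= 1L) kid else br[cur]
      queue <- c(queue, kid)
    }
  }
  br
}

#' Classify metamers into trunk and whole first-order branches
#'
#' Trunk group = the order-0 axis (current-year extension included); each
#' subtree rooted at a branching child of a trunk metamer is one group,
#' with all its shoots; the root compartment is its own group.
#'
#' @param tree a `mst` object.
#' @return named character vector of group labels over metamers.
#' @export
classify_br1 <- function(tree) {
  vs <- vertices_at(tree, finest_scale(tree))
  ot <- tree$props[vs, "organ_type"]
  ord <- branching_order(tree)
  lab <- stats::setNames(rep(NA_character_, length(vs)), vs)
  lab[ot == "root_compartment"] <- "root"
  lab[is.na(lab) & ord == 0L] <- "trunk"
  rest <- vs[is.na(lab)]
  if (length(rest)) {
    broot <- .branch_root(tree, vs, ord)
    lab[rest] <- paste0("br1.", broot[rest])
  }
  lab
}

#' Classify metamers into fruiting units
#'
#' A fruiting unit is a maximal connected section of wood aged exactly one
#' year together with all current-year shoots borne on it.  All remaining
#' wood (and current-year growth borne directly on it) forms a single
#' supporting-structure group; the root compartment is its own group.  A
#' tree with no wood older than the current year degenerates to a single
#' fruiting unit.
#'
#' @param tree a `mst` object with a `year` property on every metamer.
#' @return named character vector of group labels over metamers.
#' @export
classify_fu <- function(tree) {
  vs <- vertices_at(tree, finest_scale(tree))
  ot <- tree$props[vs, "organ_type"]
  year <- tree$props[vs, "year"]
  if (anyNA(year[ot != "root_compartment"])) {
    stop("metamer '", vs[which(is.na(year) & ot != "root_compartment")[1]],
         "' has no year property")
  }
  cy <- max(year, na.rm = TRUE)
  lab <- stats::setNames(rep(NA_character_, length(vs)), vs)
  lab[ot == "root_compartment"] <- "root"

  plant_vs <- vs[ot != "root_compartment"]
  if (all(year[match(plant_vs, vs)] == cy)) {
    lab[plant_vs] <- "FU.all"        # degenerate: all current-year growth
    return(lab)
  }

  # connected sections of 1-year-old wood, labelled by their base vertex
  oyo <- plant_vs[year[match(plant_vs, vs)] == cy - 1]
  sec <- stats::setNames(rep(NA_character_, length(oyo)), oyo)
  for (v in oyo) {
    chain <- v
    w <- v
    repeat {
      p <- tree$parent[[w]]
      if (is.na(p) || !(p %in% oyo)) break
      if (!is.na(sec[p])) { sec[chain] <- sec[p]; chain <- character(0); break }
      chain <- c(chain, p)
      w <- p
    }
    if (length(chain)) sec[chain] <- w
  }
  lab[oyo] <- paste0("FU.", sec)

  # current-year subtrees attach to the unit (or support) of their bearer
  sub <- .current_year_subtrees(tree)
  for (b in unique(sub)) {
    members <- names(sub)[sub == b]
    p <- tree$parent[[b]]
    lab[members] <- if (!is.na(p) && p %in% oyo) {
      paste0("FU.", sec[[p]])
    } else "support"
  }
  lab[is.na(lab)] <- "support"
  lab
}

#' Insert a new scale into a two-scale tree
#'
#' Groups the metamers according to the rule in `spec` and inserts the
#' resulting scale between the plant scale and the metamer scale.  The
#' coarse parent and edge type of each group are derived from the
#' finest-scale edge crossing the group boundary at its base; the coarse
#' length and leaf area are the sums over components.
#'
#' @param tree a `mst` with exactly two scales (plant, M).  Trees carrying
#'   a previously built scale are refused; build each working scale from
#'   the base tree.
#' @param spec a [scale_spec()] (or a name understood by it).
#' @return a validated `mst` with three scales.
#' @export
build_scale <- function(tree, spec) {
  if (is.character(spec)) spec <- scale_spec(spec)
  if (length(tree$scale_names) != 2L) {
    stop("build_scale expects a base tree with scales (plant, M); ",
         "build each working scale from the base tree")
  }
  vs <- vertices_at(tree, "M")
  lab <- spec$rule(tree)
  lab <- lab[vs]
  if (anyNA(lab)) {
    stop("grouping rule left metamer '", vs[which(is.na(lab))[1]],
         "' without a group")
  }
  ot <- tree$props[vs, "organ_type"]
  lab[ot == "root_compartment"] <- "root"   # always its own group

  groups <- split(vs, lab)
  # connectivity + base identification
  base_of <- vapply(names(groups), function(g) {
    .check_group_connected(tree, groups[[g]], paste0("group '", g, "'"))
  }, character(1))

  # deterministic coarse ids, ordered by base vertex id
  gnames <- names(groups)[order(base_of)]
  gid <- stats::setNames(sprintf("%s.%03d", spec$name, seq_along(gnames)),
                         gnames)
  group_of <- stats::setNames(gid[lab], vs)

  plant <- tree$vertex[tree$scale == 1L]
  new_vertex <- unname(gid[gnames])
  new_parent <- new_edge <- stats::setNames(
    rep(NA_character_, length(new_vertex)), new_vertex)
  for (g in gnames) {
    b <- base_of[[g]]
    p <- tree$parent[[b]]
    if (!is.na(p)) {
      new_parent[gid[[g]]] <- group_of[[p]]
      new_edge[gid[[g]]] <- tree$edge[[b]]
    }
  }
  glen <- vapply(gnames, function(g)
    sum(tree$props[groups[[g]], "length"], na.rm = TRUE), numeric(1))
  gla <- vapply(gnames, function(g)
    sum(tree$props[groups[[g]], "leaf_area"], na.rm = TRUE), numeric(1))

  vertex <- c(tree$vertex, new_vertex)
  scale <- c(ifelse(tree$scale == 1L, 1L, 3L), rep(2L, length(new_vertex)))
  parent <- c(tree$parent, new_parent)
  edge <- c(tree$edge, new_edge)
  complex <- c(ifelse(tree$scale == 1L, NA_character_,
                      group_of[tree$vertex]),
               rep(plant, length(new_vertex)))
  props <- tree$props
  newp <- data.frame(
    organ_type = ifelse(gnames == "root", "root_compartment", "wood"),
    year = NA_real_, top_x = NA_real_, top_y = NA_real_, top_z = NA_real_,
    radius = NA_real_, length = unname(glen), leaf_area = unname(gla),
    has_fruit = NA_real_, gu = NA_character_,
    stringsAsFactors = FALSE, row.names = unname(gid[gnames])
  )
  props <- rbind(props, newp)
  out <- mst_create(vertex, scale, parent, edge, complex,
                    props[vertex, , drop = FALSE],
                    scale_names = c(tree$scale_names[1], spec$name, "M"))
  out$organs <- tree$organs
  out
}
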