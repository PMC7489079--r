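#' Multi-scale tree graphs
#'
#' A `mst` object represents a plant as a multi-scale tree graph (MTG): a
#' set of vertices, each living at one topological scale, connected by
#' same-scale parent/child edges (succession `"<"` or branching `"+"`) and
#' by complex/component links across adjacent scales.  Scale 1 is the
#' coarsest container (the whole plant); the highest scale index is the
#' metamer scale.  The root system is one opaque vertex of organ type
#' `root_compartment` placed below the trunk base at the metamer scale.
#'
#' Internally the object is a list with components `vertex` (character ids,
#' kept sorted so every traversal is deterministic), `scale`, `parent`,
#' `edge`, `complex` (named vectors over vertices), `props` (a data.frame of
#' per-vertex properties: `organ_type`, `year`, `top_x/y/z` in metres,
#' `radius`, `length` in metres, `leaf_area` in m^2, `has_fruit`,
#' `gu` label), `scale_names` (character, index = scale), and optionally
#' `organs` (see [init_biomass()]).
#'
#' @name mst
NULL

.mst_prop_cols <- c("organ_type", "year", "top_x", "top_y", "top_z",
                    "radius", "length", "leaf_area", "has_fruit", "gu")

#' Construct a multi-scale tree
#'
#' Low-level constructor.  Most users build trees with [read_mtg()],
#' [mst_from_table()] or [generate_tree()].
#'
#' @param vertex character vector of unique vertex ids.
#' @param scale integer scale index per vertex (1 = coarsest).
#' @param parent same-scale parent id per vertex, `NA` for each scale root.
#' @param edge edge type to the parent, `"<"` (succession) or `"+"`
#'   (branching); `NA` where `parent` is `NA`.
#' @param complex containing vertex at the next-coarser scale, `NA` at
#'   scale 1.
#' @param props data.frame of per-vertex properties (missing columns are
#'   filled with `NA`); row order must match `vertex`.
#' @param scale_names character vector naming the scales, index = scale.
#' @param validate run [validate_mst()] on the result.
#' @return an object of class `mst`.
#' @export
mst_create <- function(vertex, scale, parent, edge, complex, props = NULL,
                       scale_names = c("plant", "M"), validate = TRUE) {
  vertex <- as.character(vertex)
  ord <- order(vertex)
  if (is.null(props)) {
    props <- data.frame(row.names = vertex)
  }
  for (cc in .mst_prop_cols) {
    if (is.null(props[[cc]])) {
      props[[cc]] <- if (cc == "organ_type" || cc == "gu") NA_character_ else NA_real_
    }
  }
  props <- props[, .mst_prop_cols, drop = FALSE]
  tree <- structure(list(
    vertex = vertex[ord],
    scale = stats::setNames(as.integer(scale)[ord], vertex[ord]),
    parent = stats::setNames(as.character(parent)[ord], vertex[ord]),
    edge = stats::setNames(as.character(edge)[ord], vertex[ord]),
    complex = stats::setNames(as.character(complex)[ord], vertex[ord]),
    props = {
      p <- props[ord, , drop = FALSE]
      rownames(p) <- vertex[ord]
      p
    },
    scale_names = as.character(scale_names)
  ), class = "mst")
  if (validate) validate_mst(tree)
  tree
}

#' @export
print.mst <- function(x, ...) {
  cat("Multi-scale tree graph\n")
  for (s in seq_along(x$scale_names)) {
    cat(sprintf("  scale %d (%s): %d vertices\n", s, x$scale_names[s],
                sum(x$scale == s)))
  }
  if (!is.null(x$organs)) {
    cat(sprintf("  organs: %d (biomass initialized)\n", nrow(x$organs)))
  }
  invisible(x)
}

#' Index of the finest (metamer) scale
#' @param tree a `mst` object.
#' @return integer scale index.
#' @export
finest_scale <- function(tree) length(tree$scale_names)

#' Resolve a scale name to its index
#' @param tree a `mst` object.
#' @param scale_name scale name (e.g. `"M"`, `"GU"`) or integer index.
#' @return integer scale index.
#' @export
scale_index <- function(tree, scale_name) {
  if (is.numeric(scale_name)) {
    s <- as.integer(scale_name)
    if (s < 1L || s > length(tree$scale_names)) {
      stop("unknown scale index: ", scale_name)
    }
    return(s)
  }
  s <- match(scale_name, tree$scale_names)
  if (is.na(s)) {
    stop("unknown scale name: '", scale_name, "' (tree has: ",
         paste(tree$scale_names, collapse = ", "), ")")
  }
  s
}

#' Vertices at a scale
#' @inheritParams scale_index
#' @return character vector of vertex ids, ascending.
#' @export
vertices_at <- function(tree, scale_name) {
  tree$vertex[tree$scale[tree$vertex] == scale_index(tree, scale_name)]
}

#' Validate a multi-scale tree
#'
#' Checks the structural invariants: unique ids; one root per scale with
#' all same-scale vertices forming a single tree (no cycles); parents at
#' the same scale; every vertex below scale 1 has a complex at the
#' next-coarser scale; the components of every complex form a connected
#' subtree with a unique base (the one component whose parent lies outside
#' the complex); nonnegative lengths, radii, leaf areas.
#'
#' @param tree a `mst` object.
#' @return `tree`, invisibly; errors name the offending vertex.
#' @export
validate_mst <- function(tree) {
  v <- tree$vertex
  if (anyDuplicated(v)) stop("duplicated vertex ids")
  ns <- length(tree$scale_names)
  if (any(tree$scale < 1L | tree$scale > ns)) {
    stop("vertex with scale outside 1..", ns, ": ",
         v[which(tree$scale < 1L | tree$scale > ns)[1]])
  }
  has_par <- !is.na(tree$parent)
  bad <- has_par & !(tree$parent %in% v)
  if (any(bad)) stop("parent of vertex '", v[bad][1], "' does not exist")
  bad <- has_par & tree$scale[tree$parent[v]] != tree$scale[v]
  bad[is.na(bad)] <- FALSE
  if (any(bad)) stop("parent of vertex '", v[which(bad)[1]],
                     "' is at a different scale")
  bad <- has_par & !(tree$edge %in% c("<", "+"))
  if (any(bad)) stop("vertex '", v[which(bad)[1]],
                     "' has invalid edge type '", tree$edge[which(bad)[1]], "'")
  for (s in seq_len(ns)) {
    vs <- v[tree$scale[v] == s]
    if (!length(vs)) stop("scale ", s, " ('", tree$scale_names[s],
                          "') has no vertices")
    roots <- vs[is.na(tree$parent[vs])]
    if (length(roots) != 1L) {
      stop("scale ", s, " must have exactly one root, found ",
           length(roots), if (length(roots)) paste0(": ",
           paste(utils::head(roots, 3), collapse = ", ")) else "")
    }
    # cycle / connectivity check by walking to the root from every vertex
    depth <- .mst_depths(tree, vs)
    if (anyNA(depth)) {
      stop("cycle or disconnection at scale ", s, " involving vertex '",
           vs[which(is.na(depth))[1]], "'")
    }
  }
  # complex links
  not_coarsest <- v[tree$scale[v] > 1L]
  bad <- not_coarsest[is.na(tree$complex[not_coarsest])]
  if (length(bad)) stop("vertex '", bad[1], "' has no complex")
  cx <- tree$complex[not_coarsest]
  if (any(!(cx %in% v))) {
    stop("complex of vertex '", not_coarsest[which(!(cx %in% v))[1]],
         "' does not exist")
  }
  if (any(tree$scale[cx] != tree$scale[not_coarsest] - 1L)) {
    stop("complex of vertex '",
         not_coarsest[which(tree$scale[cx] != tree$scale[not_coarsest] - 1L)[1]],
         "' is not at the next-coarser scale")
  }
  for (I in v[tree$scale[v] < ns]) {
    comp <- v[!is.na(tree$complex[v]) & tree$complex[v] == I]
    if (!length(comp)) next
    .check_group_connected(tree, comp, paste0("components of complex '", I, "'"))
  }
  num <- tree$props[, c("radius", "length", "leaf_area"), drop = FALSE]
  for (cc in names(num)) {
    bad <- which(!is.na(num[[cc]]) & num[[cc]] < 0)
    if (length(bad)) {
      stop("vertex '", rownames(tree$props)[bad[1]], "' has negative ", cc)
    }
  }
  invisible(tree)
}

# depth of each vertex within its scale; NA signals a cycle
.mst_depths <- function(tree, vs) {
  depth <- stats::setNames(rep(NA_real_, length(vs)), vs)
  n <- length(vs)
  for (v0 in vs) {
    cur <- v0
    steps <- 0L
    path <- character(0)
    while (is.na(depth[cur])) {
      path <- c(path, cur)
      p <- tree$parent[[cur]]
      if (is.na(p)) { depth[cur] <- 0; break }
      if (!is.na(depth[p])) { break }
      cur <- p
      steps <- steps + 1L
      if (steps > n) return(stats::setNames(rep(NA_real_, length(vs)), vs))
    }
    # unwind
    for (w in rev(path)) {
      p <- tree$parent[[w]]
      if (!is.na(p)) depth[w] <- depth[p] + 1
    }
  }
  depth
}

# error unless `group` (same-scale vertex ids) forms a connected subtree
# with a unique base whose parent lies outside the group
.check_group_connected <- function(tree, group, what) {
  inside <- stats::setNames(rep(TRUE, length(group)), group)
  par <- tree$parent[group]
  base <- group[is.na(par) | !(par %in% group)]
  if (length(base) != 1L) {
    stop(what, " are disconnected (", length(base),
         " base vertices: ", paste(utils::head(base, 4), collapse = ", "), ")")
  }
  invisible(base)
}

#' Components of a complex
#'
#' Returns the components (vertices at the next-finer scale) of a vertex,
#' base component first, then in breadth-first topological order within the
#' group (ties broken by ascending id).
#'
#' @param tree a `mst` object.
#' @param vertex a vertex id not at the finest scale.
#' @return character vector of component ids.
#' @export
components_of <- function(tree, vertex) {
  if (!vertex %in% tree$vertex) stop("unknown vertex: ", vertex)
  if (tree$scale[[vertex]] == finest_scale(tree)) {
    stop("vertex '", vertex, "' is at the finest scale and has no components")
  }
  comp <- tree$vertex[!is.na(tree$complex) & tree$complex == vertex]
  if (!length(comp)) return(character(0))
  base <- .check_group_connected(tree, comp,
                                 paste0("components of '", vertex, "'"))
  # BFS from the base within the group
  out <- character(length(comp))
  out[1] <- base
  seen <- stats::setNames(logical(length(comp)), comp)
  seen[base] <- TRUE
  k <- 1L
  queue <- base
  kids_of <- split(comp[!is.na(tree$parent[comp])],
                   tree$parent[comp][!is.na(tree$parent[comp])])
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    kids <- sort(kids_of[[cur]])
    kids <- kids[!seen[kids]]
    for (kid in kids) {
      k <- k + 1L
      out[k] <- kid
      seen[kid] <- TRUE
    }
    queue <- c(queue, kids)
  }
  out
}

#' Count the components of a tree at one scale
#'
#' The root compartment counts as one component, matching how component
#' numbers are reported per scale in multi-scale allocation studies.
#'
#' @inheritParams scale_index
#' @return integer count of vertices at the scale.
#' @export
count_components <- function(tree, scale_name) {
  length(vertices_at(tree, scale_name))
}

#' Same-scale root of a scale
#' @inheritParams scale_index
#' @return vertex id of the scale's root.
#' @export
scale_root <- function(tree, scale_name) {
  vs <- vertices_at(tree, scale_name)
  vs[is.na(tree$parent[vs])]
}

#' Build a base two-scale tree from a metamer table
#'
#' Constructs a `mst` with a single plant-scale container plus the metamer
#' scale from one row per metamer.  A `root_compartment` row may be present
#' (a row whose `organ_type` is `"root_compartment"`); if absent, one is
#' inserted below the metamer-scale root with zero length at the root's
#' base position.
#'
#' @param df data.frame with columns `vertex_id`, `parent_id` (empty/NA for
#'   the root row), `edge_type`, `organ_type`, `year`, `top_x`, `top_y`,
#'   `top_z`, `radius`, `length`, `leaf_area`, optional `has_fruit`, `gu`.
#' @param unit unit of the input coordinates/lengths: `"m"`, `"cm"` or
#'   `"mm"`; everything is stored in metres.
#' @param plant_id id for the plant-scale vertex.
#' @return a validated `mst`.
#' @export
mst_from_table <- function(df, unit = c("m", "cm", "mm"), plant_id = "P1") {
  unit <- match.arg(unit)
  fac <- c(m = 1, cm = 0.01, mm = 0.001)[[unit]]
  need <- c("vertex_id", "parent_id", "edge_type", "organ_type", "year",
            "top_x", "top_y", "top_z", "radius", "length", "leaf_area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$parent_id[df$parent_id %in% c("", "NA")] <- NA_character_
  if (is.null(df$has_fruit)) df$has_fruit <- 0
  if (is.null(df$gu)) df$gu <- NA_character_

  if (!any(df$organ_type == "root_compartment")) {
    root_row <- which(is.na(df$parent_id))
    if (length(root_row) != 1L) {
      stop("expected exactly one root row, found ", length(root_row))
    }
    rid <- "ROOT0"
    rc <- df[root_row, ]
    rc$vertex_id <- rid
    rc$parent_id <- NA_character_
    rc$edge_type <- NA_character_
    rc$organ_type <- "root_compartment"
    # root compartment sits at the trunk base; infer the base of the first
    # metamer from explicit base_* columns, else back along the direction
    # towards its first child, else straight down
    rtop <- as.numeric(df[root_row, c("top_x", "top_y", "top_z")])
    if (all(c("base_x", "base_y", "base_z") %in% names(df)) &&
        !anyNA(df[root_row, c("base_x", "base_y", "base_z")])) {
      rbase <- as.numeric(df[root_row, c("base_x", "base_y", "base_z")])
    } else {
      kid <- which(df$parent_id == df$vertex_id[root_row])[1]
      dirv <- if (!is.na(kid)) {
        as.numeric(df[kid, c("top_x", "top_y", "top_z")]) - rtop
      } else c(0, 0, 1)
      nv <- sqrt(sum(dirv^2))
      if (nv == 0) dirv <- c(0, 0, 1) else dirv <- dirv / nv
      rbase <- rtop - df$length[root_row] * dirv
    }
    rc[, c("top_x", "top_y", "top_z")] <- rbase
    rc$length <- 0
    rc$radius <- 0
    rc$leaf_area <- 0
    rc$has_fruit <- 0
    rc$gu <- NA_character_
    rc$year <- NA
    df$parent_id[root_row] <- rid
    df$edge_type[root_row] <- "<"
    df <- rbind(rc, df)
  }

  n <- nrow(df)
  root_row <- which(is.na(df$parent_id))
  vertex <- c(plant_id, df$vertex_id)
  scale <- c(1L, rep(2L, n))
  parent <- c(NA_character_, df$parent_id)
  edge <- c(NA_character_, df$edge_type)
  complex <- c(NA_character_, rep(plant_id, n))
  props <- data.frame(
    organ_type = c(NA_character_, df$organ_type),
    year = c(NA_real_, as.numeric(df$year)),
    top_x = c(df$top_x[root_row], df$top_x) * fac,
    top_y = c(df$top_y[root_row], df$top_y) * fac,
    top_z = c(df$top_z[root_row], df$top_z) * fac,
    radius = c(NA_real_, df$radius) * fac,
    length = c(NA_real_, df$length) * fac,
    leaf_area = c(NA_real_, df$leaf_area),
    has_fruit = c(NA_real_, as.numeric(df$has_fruit)),
    gu = c(NA_character_, as.character(df$gu)),
    stringsAsFactors = FALSE
  )
  # plant-scale vertex stores the base coordinates of the tree root
  mst_create(vertex, scale, parent, edge, complex, props,
             scale_names = c("plant", "M"))
}
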