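#' Annotate bases, barycentres and semi-lengths at a scale
#'
#' At the metamer scale the base of a vertex is the top of its parent (the
#' tree root inherits its base coordinates from its complex) and the
#' barycentre is the midpoint of base and top.  At a coarse scale the base
#' of a vertex is the base of its base component (the component whose
#' parent lies outside the complex) and the barycentre is the mean of the
#' component barycentres weighted by their individual lengths.  The
#' semi-length is the Euclidean distance from base to barycentre; the
#' length of a coarse vertex is the sum of its component lengths.
#'
#' @param tree a `mst` object with metamer-scale top coordinates.
#' @param scale_name scale to annotate (defaults to the finest scale).
#' @return a data.frame (one row per vertex at the scale, ascending id)
#'   with columns `vertex`, `base_x/y/z`, `bary_x/y/z`, `length`,
#'   `semi_length`; the scale name is stored in attribute `"scale"`.
#' @export
annotate_geometry <- function(tree, scale_name = finest_scale(tree)) {
  s <- scale_index(tree, scale_name)
  fs <- finest_scale(tree)
  vs <- vertices_at(tree, fs)
  top <- as.matrix(tree$props[vs, c("top_x", "top_y", "top_z")])
  if (anyNA(top)) {
    stop("missing top coordinates for metamer '", vs[which(rowSums(is.na(top)) > 0)[1]], "'")
  }
  par <- tree$parent[vs]
  base <- top
  has_par <- !is.na(par)
  base[has_par, ] <- top[match(par[has_par], vs), ]
  root <- vs[!has_par]
  cx <- tree$complex[[root]]
  # base coordinates of the tree root live on its complex chain (coarsest)
  while (!is.na(tree$complex[[cx]])) cx <- tree$complex[[cx]]
  rb <- as.numeric(tree$props[cx, c("top_x", "top_y", "top_z")])
  if (anyNA(rb)) rb <- top[match(root, vs), ]
  base[match(root, vs), ] <- rb
  bary <- (top + base) / 2
  len <- tree$props[vs, "length"]
  geomM <- data.frame(
    vertex = vs,
    base_x = base[, 1], base_y = base[, 2], base_z = base[, 3],
    bary_x = bary[, 1], bary_y = bary[, 2], bary_z = bary[, 3],
    length = len,
    semi_length = sqrt(rowSums((bary - base)^2)),
    stringsAsFactors = FALSE
  )
  rownames(geomM) <- vs
  if (s == fs) {
    attr(geomM, "scale") <- tree$scale_names[s]
    return(geomM)
  }
  if (s == 1L) stop("cannot annotate geometry at the plant scale")
  # one intermediate scale: components are the metamers themselves
  cs <- vertices_at(tree, s)
  comp_of <- split(vs, tree$complex[vs])
  out <- data.frame(
    vertex = cs, base_x = NA_real_, base_y = NA_real_, base_z = NA_real_,
    bary_x = NA_real_, bary_y = NA_real_, bary_z = NA_real_,
    length = NA_real_, semi_length = NA_real_, stringsAsFactors = FALSE
  )
  rownames(out) <- cs
  for (I in cs) {
    comp <- comp_of[[I]]
    b <- comp[is.na(tree$parent[comp]) | !(tree$parent[comp] %in% comp)]
    w <- geomM[comp, "length"]
    if (sum(w) <= 0) w <- rep(1, length(comp))   # zero-length group (root)
    bar <- colSums(geomM[comp, c("bary_x", "bary_y", "bary_z")] * w) / sum(w)
    out[I, c("base_x", "base_y", "base_z")] <-
      geomM[b, c("base_x", "base_y", "base_z")]
    out[I, c("bary_x", "bary_y", "bary_z")] <- bar
    out[I, "length"] <- sum(geomM[comp, "length"])
    out[I, "semi_length"] <- sqrt(sum((bar - as.numeric(
      geomM[b, c("base_x", "base_y", "base_z")]))^2))
  }
  attr(out, "scale") <- tree$scale_names[s]
  out
}

#' Greatest common ancestor of two vertices
#'
#' The deepest vertex contained in both root-paths.  `gca(v, v) = v` and
#' `gca(root, v) = root`.
#'
#' @param tree a `mst` object.
#' @param i,j vertex ids at the same scale.
#' @param scale_name scale of `i` and `j` (checked).
#' @return vertex id of the greatest common ancestor.
#' @export
gca <- function(tree, i, j, scale_name = NULL) {
  if (tree$scale[[i]] != tree$scale[[j]]) {
    stop("vertices '", i, "' and '", j, "' are at different scales")
  }
  if (!is.null(scale_name) &&
      tree$scale[[i]] != scale_index(tree, scale_name)) {
    stop("vertices are not at scale '", scale_name, "'")
  }
  ai <- .root_path(tree, i)
  aj <- .root_path(tree, j)
  k <- 1L
  m <- min(length(ai), length(aj))
  while (k <= m && ai[k] == aj[k]) k <- k + 1L
  if (k == 1L) stop("internal error: vertices share no ancestor")
  ai[k - 1L]
}

# path from the scale root down to v (root first, v last)
.root_path <- function(tree, v) {
  path <- character(0)
  cur <- v
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- tree$parent[[cur]]
  }
  rev(path)
}

#' Topological distance between two vertices
#'
#' Distance along the plant topology between the barycentres of `i` and
#' `j`: the two semi-lengths, plus the lengths of the path-internal
#' elements.  When the greatest common ancestor (GCA) is neither `i` nor
#' `j`, both path sides stop at the elements directly borne on the GCA and
#' the straight-line (Euclidean) distance between the bases of those two
#' elements is added; the GCA's own length does not contribute.  When the
#' GCA is `i` or `j`, the distance is the sum of the strictly internal
#' element lengths plus the two semi-lengths.  `dist(i, i) = 0`.
#'
#' @param tree a `mst` object.
#' @param geometry output of [annotate_geometry()] at the vertices' scale.
#' @param i,j vertex ids at the annotated scale.
#' @return distance in metres.
#' @export
pairwise_distance <- function(tree, geometry, i, j) {
  if (i == j) return(0)
  ai <- .root_path(tree, i)
  aj <- .root_path(tree, j)
  k <- 1L
  m <- min(length(ai), length(aj))
  while (k <= m && ai[k] == aj[k]) k <- k + 1L
  g <- ai[k - 1L]
  semi <- geometry[c(i, j), "semi_length"]
  if (g == i || g == j) {
    # ancestor case: internal elements strictly between i and j
    long <- if (length(ai) > length(aj)) ai else aj
    internal <- if (k <= length(long) - 1L) long[k:(length(long) - 1L)]
                else character(0)
    return(sum(geometry[internal, "length"]) + sum(semi))
  }
  ci <- ai[k]                      # element of i's path borne on the GCA
  cj <- aj[k]
  int_i <- if (k <= length(ai) - 1L) ai[k:(length(ai) - 1L)] else character(0)
  int_j <- if (k <= length(aj) - 1L) aj[k:(length(aj) - 1L)] else character(0)
  gap <- sqrt(sum((as.numeric(geometry[ci, c("base_x", "base_y", "base_z")]) -
                   as.numeric(geometry[cj, c("base_x", "base_y", "base_z")]))^2))
  sum(semi) + sum(geometry[int_i, "length"]) +
    sum(geometry[int_j, "length"]) + gap
}

#' Pairwise distance matrix between sources and sinks
#'
#' Computes all source-sink topological distances at one scale with shared
#' root-path caching, so the cost is near-quadratic in the number of
#' components at the working scale rather than in the number of metamers.
#'
#' @param tree a `mst` object.
#' @param geometry output of [annotate_geometry()] at `scale_name`.
#' @param scale_name working scale.
#' @param sources,sinks vertex ids at the scale (defaults: all).
#' @return a `sources` x `sinks` numeric matrix of metres, with dimnames.
#' @export
distance_matrix <- function(tree, geometry, scale_name,
                            sources = NULL, sinks = NULL) {
  s <- scale_index(tree, scale_name)
  vs <- vertices_at(tree, s)
  if (is.null(sources)) sources <- vs
  if (is.null(sinks)) sinks <- vs
  stopifnot(all(sources %in% vs), all(sinks %in% vs))
  ids <- sort(unique(c(sources, sinks)))
  np <- lapply(stats::setNames(ids, ids), function(v) .root_path(tree, v))
  # cumulative length from the root along each root path
  lens <- stats::setNames(geometry[vs, "length"], vs)
  semis <- stats::setNames(geometry[vs, "semi_length"], vs)
  bases <- as.matrix(geometry[vs, c("base_x", "base_y", "base_z")])
  rownames(bases) <- vs
  cum <- lapply(np, function(p) cumsum(lens[p]))
  D <- matrix(0, length(sources), length(sinks),
              dimnames = list(sources, sinks))
  for (a in sources) {
    pa <- np[[a]]; ca <- cum[[a]]; na <- length(pa)
    for (b in sinks) {
      if (a == b) next
      if (a > b && b %in% sources && a %in% sinks) {
        D[a, b] <- D[b, a]          # symmetry
        next
      }
      pb <- np[[b]]; cb <- cum[[b]]; nb <- length(pb)
      m <- min(na, nb)
      k <- 1L
      while (k <= m && pa[k] == pb[k]) k <- k + 1L
      kg <- k - 1L
      if (kg == na || kg == nb) {
        # one is the ancestor of the other
        if (na > nb) {
          internal <- ca[na - 1L] - ca[kg]
        } else {
          internal <- cb[nb - 1L] - cb[kg]
        }
        D[a, b] <- internal + semis[[a]] + semis[[b]]
      } else {
        gap <- sqrt(sum((bases[pa[k], ] - bases[pb[k], ])^2))
        D[a, b] <- semis[[a]] + semis[[b]] +
          (ca[na - 1L] - ca[kg]) + (cb[nb - 1L] - cb[kg]) + gap
      }
    }
  }
  D
}
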