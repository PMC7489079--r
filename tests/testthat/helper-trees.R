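# fixture builders and independent oracles shared across test files

# straight chain of n unit-ish metamers along x
chain_tree <- function(n, len = 1, year = 1) {
  df <- data.frame(
    vertex_id = sprintf("c%02d", seq_len(n)),
    parent_id = c(NA, sprintf("c%02d", seq_len(n - 1))),
    edge_type = c(NA, rep("<", n - 1)),
    organ_type = "internode", year = year,
    top_x = seq_len(n) * len, top_y = 0, top_z = 0,
    radius = 0.01, length = len, leaf_area = 0,
    gu = "g1", stringsAsFactors = FALSE
  )
  mst_from_table(df)
}

# random geometric tree: random topology, straight segments whose stored
# length equals the geometric step, random directions
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, sprintf("r%03d", sapply(2:n, function(k) sample(k - 1, 1))))
  len <- stats::runif(n, 0.2, 1.5)
  theta <- stats::runif(n, 0, 2 * pi)
  phi <- stats::runif(n, 0, pi / 2)
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  top <- matrix(0, n, 3)
  ids <- sprintf("r%03d", seq_len(n))
  nkids <- integer(n)
  edge <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    base <- if (k == 1) c(0, 0, 0) else top[match(parent[k], ids), ]
    top[k, ] <- base + len[k] * dirs[k, ]
    if (k > 1) {
      pi_ <- match(parent[k], ids)
      edge[k] <- if (nkids[pi_] == 0) "<" else "+"
      nkids[pi_] <- nkids[pi_] + 1L
    }
  }
  # connected random grouping: a vertex starts a new group or joins its
  # parent's, so every group is a connected subtree
  gu <- character(n)
  starts <- stats::runif(n) < 0.3
  gu[1] <- "g1"
  for (k in 2:n) {
    gu[k] <- if (starts[k]) ids[k] else gu[match(parent[k], ids)]
  }
  df <- data.frame(
    vertex_id = ids, parent_id = parent, edge_type = edge,
    organ_type = "internode", year = 1,
    top_x = top[, 1], top_y = top[, 2], top_z = top[, 3],
    radius = 0.01, length = len, leaf_area = 0,
    gu = gu,
    stringsAsFactors = FALSE
  )
  mst_from_table(df)
}

# independent ancestor-set oracle for the greatest common ancestor
gca_oracle <- function(tree, i, j) {
  anc <- function(v) {
    out <- character(0)
    while (!is.na(v)) { out <- c(out, v); v <- tree$parent[[v]] }
    out
  }
  ai <- anc(i); aj <- anc(j)
  common <- intersect(ai, aj)
  # deepest = the common ancestor whose ancestor set is largest
  common[which.max(vapply(common, function(v) length(anc(v)), numeric(1)))]
}

# independent path-walk distance oracle: builds the explicit vertex path,
# then applies the subtraction form: the two semi-lengths plus the path
# lengths down to the GCA (GCA included on both sides), minus twice the
# GCA length, plus the Euclidean gap between the bases of the two
# elements borne on the GCA; ancestor case sums strictly-internal lengths
dist_oracle <- function(tree, geometry, i, j) {
  if (i == j) return(0)
  anc <- function(v) {
    out <- character(0)
    while (!is.na(v)) { out <- c(out, v); v <- tree$parent[[v]] }
    out
  }
  ai <- anc(i); aj <- anc(j)          # vertex .. root
  g <- gca_oracle(tree, i, j)
  semi <- function(v) geometry[v, "semi_length"]
  len <- function(v) sum(geometry[v, "length"])
  if (g == i || g == j) {
    deep <- if (g == i) aj else ai
    internal <- deep[-1]                           # drop the deep endpoint
    internal <- internal[seq_len(match(g, internal) - 1)]  # strictly inside
    return(semi(i) + semi(j) + len(internal))
  }
  side <- function(av) av[2:match(g, av)]          # parent .. GCA inclusive
  first_on_g <- function(av) av[match(g, av) - 1]  # element borne on the GCA
  bse <- function(v) as.numeric(geometry[v, c("base_x", "base_y", "base_z")])
  gap <- sqrt(sum((bse(first_on_g(ai)) - bse(first_on_g(aj)))^2))
  semi(i) + len(side(ai)) + len(side(aj)) + semi(j) - 2 * len(g) + gap
}

# apple-like base tree with biomass + supplies, shared by heavier tests
apple_fixture <- function(seed = 11, gdd_cum = 800, ...) {
  cf <- synth_config(seed = seed, ...)
  tree <- init_biomass(generate_tree(cf), gdd_cum = gdd_cum)
  supply <- load_supply(tree, generate_supply(tree, cf))
  list(tree = tree, supply = supply, config = cf, gdd_cum = gdd_cum)
}
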