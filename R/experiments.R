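#' Default neighbourhood radii (metres)
#'
#' The eleven radii used for the fruit-competition neighbourhood analysis.
#' @export
neighbourhood_radii <- function() {
  c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.95, 1.15, 1.35)
}

#' Fruit comfort-index correlation over neighbourhood radii
#'
#' For each fruit, the neighbourhood of radius `r` is the set of metamers
#' whose barycentre lies within Euclidean distance `r` of the barycentre
#' of the fruit's metamer.  The comfort index is the carbon assimilated in
#' the neighbourhood divided by the number of fruits it contains (the
#' focal fruit included).  Per radius, the correlation between individual
#' fruit growth and the comfort index is computed over all fruits
#' (pooled), with a Bonferroni-adjusted significance threshold of
#' 0.05 / number of radii.
#'
#' @param tree a `mst` object (metamer coordinates present).
#' @param result an `allocation_result` from a metamer-scale [run_day()].
#' @param radii neighbourhood radii in metres.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return a data.frame per radius: `radius`, `n_fruits`, `r`, `p`,
#'   `significant` (Bonferroni); per-fruit tables in attribute
#'   `"per_fruit"`.  Degenerate (zero-variance) radii get `NA`
#'   correlations.
#' @export
comfort_index_correlation <- function(tree, result,
                                      radii = neighbourhood_radii(),
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  geom <- annotate_geometry(tree, finest_scale(tree))
  org <- result$organs
  fr <- org[org$organ == "fruit", ]
  if (nrow(fr) < 3) {
    stop("fewer than 3 fruits: correlation undefined")
  }
  supply <- stats::setNames(result$state_metamer$supply,
                            result$state_metamer$vertex)
  bary <- as.matrix(geom[, c("bary_x", "bary_y", "bary_z")])
  fb <- bary[fr$vertex, , drop = FALSE]
  growth <- fr$dm_increment
  alpha <- 0.05 / length(radii)
  per_fruit <- list()
  out <- data.frame(radius = radii, n_fruits = nrow(fr),
                    r = NA_real_, p = NA_real_, significant = NA)
  for (k in seq_along(radii)) {
    rr <- radii[k]
    comfort <- c_sum <- numeric(nrow(fr))
    n_nb <- integer(nrow(fr))
    for (f in seq_len(nrow(fr))) {
      d <- sqrt(rowSums(sweep(bary, 2, fb[f, ])^2))
      nb <- rownames(bary)[d <= rr]
      c_sum[f] <- sum(supply[nb])
      nfr <- sum(fr$vertex %in% nb)
      n_nb[f] <- length(nb)
      comfort[f] <- c_sum[f] / max(nfr, 1)
    }
    per_fruit[[k]] <- data.frame(vertex = fr$vertex, radius = rr,
                                 c_assimilated = c_sum, n_members = n_nb,
                                 comfort = comfort, growth = growth)
    if (stats::sd(comfort) > 0 && stats::sd(growth) > 0) {
      ct <- stats::cor.test(comfort, growth, method = method, exact = FALSE)
      out$r[k] <- unname(ct$estimate)
      out$p[k] <- ct$p.value
      out$significant[k] <- ct$p.value < alpha
    }
  }
  attr(out, "per_fruit") <- do.call(rbind, per_fruit)
  attr(out, "bonferroni_alpha") <- alpha
  out
}

#' Cross-scale comparison of fruit growth
#'
#' Pairs, per coarse component containing at least one fruit, the mean
#' per-fruit growth obtained at the metamer scale within that component
#' with the mean per-fruit growth obtained at the coarse scale, and
#' summarizes the deviation with the RMSE and its coefficient of
#' variation (RMSE divided by the mean of the metamer-scale reference
#' values).
#'
#' @param result_coarse `allocation_result` from a coarse-scale run.
#' @param result_M `allocation_result` from the metamer-scale run on the
#'   same tree and supplies.
#' @param tree the `mst` carrying the coarse scale (the one used for the
#'   coarse run).
#' @param scale_name the coarse scale name.
#' @return a list with `pairs` (data.frame `component`, `growth_M`,
#'   `growth_coarse`), `rmse` and `cv_rmse`.
#' @export
cross_scale_compare <- function(result_coarse, result_M, tree, scale_name) {
  s <- scale_index(tree, scale_name)
  orgM <- result_M$organs
  orgC <- result_coarse$organs
  frM <- orgM[orgM$organ == "fruit", ]
  frC <- orgC[orgC$organ == "fruit", ]
  if (!nrow(frM)) stop("no fruit-bearing components at scale ", scale_name)
  if (s == finest_scale(tree)) {
    comp_of <- stats::setNames(frM$vertex, frM$vertex)
  } else {
    comp_of <- tree$complex[frM$vertex]
  }
  gM <- tapply(frM$dm_increment, comp_of, mean)
  gC <- tapply(frC$dm_increment, if (s == finest_scale(tree))
    frC$vertex else tree$complex[frC$vertex], mean)
  comp <- sort(intersect(names(gM), names(gC)))
  pairs <- data.frame(component = comp,
                      growth_M = as.numeric(gM[comp]),
                      growth_coarse = as.numeric(gC[comp]),
                      stringsAsFactors = FALSE)
  rmse <- sqrt(mean((pairs$growth_coarse - pairs$growth_M)^2))
  list(pairs = pairs, rmse = rmse,
       cv_rmse = rmse / mean(pairs$growth_M))
}

#' RMSE between two normalized distributions
#'
#' Each sample is normalized (z-score by default, or min-max), binned on a
#' shared equal-width grid spanning the pooled normalized range, and the
#' root-mean-square error between the two relative-frequency vectors is
#' returned.
#'
#' @param simulated,observed numeric samples (non-empty).
#' @param n_bins number of shared bins.
#' @param normalize `"zscore"` or `"minmax"`.
#' @return RMSE of relative bin frequencies.
#' @export
distribution_rmse <- function(simulated, observed, n_bins = 20,
                              normalize = c("zscore", "minmax")) {
  normalize <- match.arg(normalize)
  if (!length(simulated) || !length(observed)) stop("empty sample")
  norm <- function(x) {
    if (normalize == "zscore") {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) stop("degenerate zero-variance sample")
      (x - mean(x)) / s
    } else {
      r <- range(x)
      if (diff(r) == 0) stop("degenerate zero-variance sample")
      (x - r[1]) / diff(r)
    }
  }
  a <- norm(simulated); b <- norm(observed)
  br <- seq(min(a, b), max(a, b), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9; br[n_bins + 1] <- br[n_bins + 1] + 1e-9
  ca <- graphics::hist(a, breaks = br, plot = FALSE)$counts / length(a)
  cb <- graphics::hist(b, breaks = br, plot = FALSE)$counts / length(b)
  sqrt(mean((ca - cb)^2))
}

#' Component counts per scale
#'
#' Builds each requested scale from the base tree and tabulates the number
#' of components and its percentage of the metamer-scale count.  Given
#' several trees, per-scale mean percentages across trees are attached as
#' attribute `"mean_pct"`.
#'
#' @param trees a base `mst` or a (optionally named) list of base trees.
#' @param scales character vector of scale names ([scale_spec()]).
#' @return data.frame `tree`, `scale`, `n_components`, `pct_of_M`.
#' @export
scale_table <- function(trees, scales = c("M", "GU", "TBS", "BR1", "FU")) {
  if (inherits(trees, "mst")) trees <- list(tree = trees)
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  rows <- list()
  for (tn in names(trees)) {
    tree <- trees[[tn]]
    nM <- count_components(tree, "M")
    for (sn in scales) {
      n <- if (sn == "M") nM else {
        count_components(build_scale(tree, sn), sn)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tree = tn, scale = sn, n_components = n,
        pct_of_M = 100 * n / nM, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_pct") <- tapply(out$pct_of_M, out$scale, mean)[scales]
  out
}
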