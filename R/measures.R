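#' Cumulative parameters: total edge length and total vascular volume
#'
#' Sums over the cylinders representing vascular edges: the Euclidean
#' start-end length, and the cylinder volume pi r^2 L (mm^3 converted to
#' ml). Overlaps and gaps at junctions are deliberately ignored, as in the
#' cylinder-tree simplification. Epsilon-connector edges contribute their
#' (negligible) epsilon lengths.
#'
#' @param tree a [vascular_tree()].
#' @return Length in mm / volume in ml.
#' @export
total_edge_length <- function(tree) {
  if (nrow(tree$edges) == 0) return(0)
  sum(edge_lengths(tree))
}

#' @rdname total_edge_length
#' @export
total_vascular_volume <- function(tree) {
  e <- tree$edges
  if (nrow(e) == 0) return(0)
  sum(pi * e$radius^2 * edge_lengths(tree)) / 1000
}

root_to_end_lengths <- function(tree) {
  e <- tree$edges
  len <- edge_lengths(tree)
  pos <- match(e$parent, e$id)
  out <- stats::setNames(rep(NA_real_, nrow(e)), e$id)
  order_by_depth <- order(vapply(seq_len(nrow(e)), function(i) {
    d <- 0L; j <- i
    while (!is.na(pos[j])) { j <- pos[j]; d <- d + 1L }
    d
  }, 0L))
  for (i in order_by_depth) {
    out[i] <- len[i] + if (is.na(pos[i])) 0 else out[pos[i]]
  }
  out
}

#' Circumscribed parameters
#'
#' `maximal_vessel_length` is the intravascular distance from the root to
#' the most distant tip (maximal root-to-tip path length).
#' `path_tortuosity` is the centerline path length between two edges
#' divided by the straight-line distance between the path's endpoints
#' (start of `from`, end of `to`); 1 for straight paths. `root_radius` is
#' the radius of the root cylinder (for a measured root span, the
#' length-weighted mean is already folded into the cylinder radius).
#'
#' @param tree a [vascular_tree()].
#' @return mm (lengths), dimensionless >= 1 (tortuosity).
#' @export
maximal_vessel_length <- function(tree) {
  if (nrow(tree$edges) == 0) return(0)
  rtl <- root_to_end_lengths(tree)
  max(rtl[as.character(tip_ids(tree))])
}

#' @rdname maximal_vessel_length
#' @param from,to edge ids; `to` must be a descendant of `from` (or equal).
#' @export
path_tortuosity <- function(tree, from = NULL, to = NULL) {
  e <- tree$edges
  if (is.null(from)) from <- root_id(tree)
  if (is.null(to)) {
    rtl <- root_to_end_lengths(tree)
    tips <- as.character(tip_ids(tree))
    to <- as.integer(tips[which.max(rtl[tips])])
  }
  # walk up from `to` to `from`
  chain <- integer(0)
  j <- match(to, e$id)
  if (is.na(j)) stop("edge ", to, " not in tree")
  repeat {
    chain <- c(chain, j)
    if (e$id[j] == from) break
    if (is.na(e$parent[j]))
      stop("edges ", from, " and ", to, " do not lie on one root-to-tip path")
    j <- match(e$parent[j], e$id)
  }
  len <- sum(edge_lengths(tree)[chain])
  i0 <- match(from, e$id)
  straight <- sqrt((e$x1[match(to, e$id)] - e$x0[i0])^2 +
                     (e$y1[match(to, e$id)] - e$y0[i0])^2 +
                     (e$z1[match(to, e$id)] - e$z0[i0])^2)
  len / max(straight, .Machine$double.eps)
}

#' @rdname maximal_vessel_length
#' @export
root_radius <- function(tree) {
  tree$edges$radius[is.na(tree$edges$parent)]
}

#' Vascular density parameters
#'
#' Ratio of total edge length (mm) / total vascular volume (ml) to the
#' parenchymal volume (ml) of the territory the tree supplies or drains.
#'
#' @param tree a [vascular_tree()].
#' @param parenchymal_volume_ml parenchymal volume in ml (> 0).
#' @return mm/ml (`edge_length_density`), dimensionless fraction
#'   (`vascular_volume_fraction`).
#' @export
edge_length_density <- function(tree, parenchymal_volume_ml) {
  if (parenchymal_volume_ml <= 0) stop("parenchymal volume must be positive")
  total_edge_length(tree) / parenchymal_volume_ml
}

#' @rdname edge_length_density
#' @export
vascular_volume_fraction <- function(tree, parenchymal_volume_ml) {
  if (parenchymal_volume_ml <= 0) stop("parenchymal volume must be positive")
  total_vascular_volume(tree) / parenchymal_volume_ml
}

#' Regeneration reporting helpers
#'
#' Changes are reported as fold increase over a reference state (for
#' regeneration: the state immediately after resection) and as percent
#' recovery relative to normal livers. Raw ratios are always returned;
#' `report_fold` / `report_percent` apply the reporting rounding (one
#' decimal for folds, integer percent).
#'
#' @param value_t parameter value at the later time point.
#' @param value_ref,value_normal positive reference values.
#' @return Dimensionless ratio / percent.
#' @export
fold_increase <- function(value_t, value_ref) {
  if (any(value_ref <= 0)) stop("reference value must be positive")
  value_t / value_ref
}

#' @rdname fold_increase
#' @export
recovery_percent <- function(value_t, value_normal) {
  if (any(value_normal <= 0)) stop("normal value must be positive")
  100 * value_t / value_normal
}

#' @rdname fold_increase
#' @param x a raw fold or percent value.
#' @export
report_fold <- function(x) sprintf("%.1f", x)

#' @rdname fold_increase
#' @export
report_percent <- function(x) sprintf("%.0f%%", x)

#' Full measurement report for one vascular tree
#'
#' Assembles the circumscribed, cumulative and density parameters with
#' provenance (input summary and configuration hash). Voxel-pipeline radii
#' carry an uncertainty of about one voxel spacing; cylinder radii are
#' treated as exact for measurement purposes.
#'
#' @param tree a [vascular_tree()].
#' @param parenchymal_volume_ml parenchymal reference volume (ml).
#' @return A `measurement_report` list.
#' @export
measurement_report <- function(tree, parenchymal_volume_ml) {
  rep <- list(
    total_edge_length = total_edge_length(tree),
    total_vascular_volume = total_vascular_volume(tree),
    maximal_vessel_length = maximal_vessel_length(tree),
    path_tortuosity = path_tortuosity(tree),
    root_radius = root_radius(tree),
    parenchymal_volume = parenchymal_volume_ml,
    edge_length_density = edge_length_density(tree, parenchymal_volume_ml),
    vascular_volume_fraction =
      vascular_volume_fraction(tree, parenchymal_volume_ml))
  rep$provenance <- list(
    n_edges = nrow(tree$edges),
    n_tips = length(tip_ids(tree)),
    n_connectors = sum(tree$edges$connector),
    config_hash = rlang::hash(list(tree$edges, parenchymal_volume_ml)))
  structure(rep, class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat("<measurement_report>\n")
  cat(sprintf("  total edge length      %10.2f mm\n", x$total_edge_length))
  cat(sprintf("  total vascular volume  %10.4f ml\n", x$total_vascular_volume))
  cat(sprintf("  maximal vessel length  %10.2f mm\n", x$maximal_vessel_length))
  cat(sprintf("  path tortuosity        %10.3f\n", x$path_tortuosity))
  cat(sprintf("  root radius            %10.3f mm\n", x$root_radius))
  cat(sprintf("  parenchymal volume     %10.4f ml\n", x$parenchymal_volume))
  cat(sprintf("  edge length density    %10.2f mm/ml\n", x$edge_length_density))
  cat(sprintf("  vascular volume fract. %10.4f\n", x$vascular_volume_fraction))
  invisible(x)
}

#' Parenchymal weight/volume relation
#'
#' Liver weight and computed liver volume are strongly correlated in
#' regenerating livers; `weight_volume_regression` fits
#' volume = slope x weight + intercept, and `liver_density` summarizes
#' weight / volume in g/ml. `simulate_parenchymal_table` generates a
#' synthetic specimen table emulating that published relation (it is a
#' stand-in for real specimen data, and is labeled synthetic wherever it
#' is written).
#'
#' @param weight_g specimen weights (g).
#' @param volume_ml computed liver volumes (ml).
#' @return `weight_volume_regression`: list with `slope`, `intercept`,
#'   `r_squared`; `liver_density`: list with `mean`, `sd` (g/ml).
#' @export
weight_volume_regression <- function(weight_g, volume_ml) {
  ok <- complete.cases(weight_g, volume_ml)
  fit <- lm(volume_ml[ok] ~ weight_g[ok])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' @rdname weight_volume_regression
#' @export
liver_density <- function(weight_g, volume_ml) {
  d <- weight_g / volume_ml
  list(mean = mean(d), sd = sd(d))
}

#' @rdname weight_volume_regression
#' @param n number of specimens.
#' @param slope,intercept generating relation volume = slope*weight+intercept.
#' @param noise_sd residual SD (ml).
#' @param seed integer seed.
#' @export
simulate_parenchymal_table <- function(n = 24, slope = 0.907,
                                       intercept = 0.053, noise_sd = 0.03,
                                       seed = 1L) {
  with_seed(seed, {
    weight <- runif(n, 0.4, 1.6)
    volume <- slope * weight + intercept + rnorm(n, 0, noise_sd)
    data.frame(specimen = paste0("synthetic_", seq_len(n)),
               weight_g = weight, volume_ml = volume)
  })
}

#' @rdname weight_volume_regression
#' @param path CSV file with columns `weight_g` and `volume_ml` (an export
#'   of a specimen parameter table).
#' @export
read_parenchymal_table <- function(path) {
  if (!file.exists(path)) stop("parenchymal table not found: ", path)
  tb <- read.csv(path)
  if (!all(c("weight_g", "volume_ml") %in% names(tb)))
    stop("table must have columns weight_g and volume_ml")
  tb
}
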