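#' Visibility threshold for growth comparison
#'
#' Scan resolution is independent of specimen size, so a regenerated liver
#' shows vessels that existed earlier but were below the detection limit.
#' Under hypothetical isotropic expansion with volume fold f (length scale
#' lambda = f^(1/3)), an edge of radius >= theta = lambda * r_min at the
#' later time point would already have had radius >= r_min — hence been
#' visible — at the earlier one. Restricting the later tree to
#' "theta-visible" edges therefore removes the visibility artifact from
#' before/after comparisons.
#'
#' @param volume_fold observed parenchymal volume fold f (> 0).
#' @param r_min minimum detectable radius (mm) at the earlier time point
#'   (typically the scan resolution or the smallest radius present).
#' @return A `visibility_threshold` list: `theta` (mm), `r_min`,
#'   `lambda_expected` = f^(1/3).
#' @export
visibility_threshold <- function(volume_fold, r_min) {
  if (volume_fold <= 0 || r_min <= 0)
    stop("volume_fold and r_min must be positive")
  lambda <- volume_fold^(1 / 3)
  structure(list(theta = lambda * r_min, r_min = r_min,
                 lambda_expected = lambda),
            class = "visibility_threshold")
}

#' Restrict a tree to its theta-visible part
#'
#' Prunes, from the root down, every edge whose radius is below `theta`
#' together with its entire descendant subtree, preserving connectivity.
#' Epsilon-connector edges never trigger pruning by themselves.
#'
#' @param tree a [vascular_tree()].
#' @param theta radius threshold (mm); 0 keeps the whole tree.
#' @return The pruned [vascular_tree()] (empty-edge tree with a warning if
#'   the root itself is below threshold).
#' @export
theta_visible_subtree <- function(tree, theta) {
  stopifnot(theta >= 0)
  e <- tree$edges
  below <- e$radius < theta & !e$connector
  if (!any(below)) return(tree)
  if (below[is.na(e$parent)]) {
    warning("root edge is below the visibility threshold; empty tree returned")
    return(vascular_tree(e[0, , drop = FALSE], domain = tree$domain,
                         validate = FALSE))
  }
  prune_roots <- e$id[below]
  drop_ids <- descendant_ids(tree, prune_roots)
  e <- e[!e$id %in% drop_ids, , drop = FALSE]
  # no chain fusion here: fusing would straighten bends and distort the
  # theta-restricted length measures this subtree exists for
  vascular_tree(e, domain = tree$domain, validate = FALSE)
}

#' Expected parameter folds under isotropic expansion
#'
#' With parenchymal volume fold f and lambda = f^(1/3): radii and lengths
#' scale by lambda, the (theta-restricted) total vascular volume by
#' lambda^3 = f, edge-length density by lambda^-2, and the vascular volume
#' fraction is unchanged; branching-angle distributions are unchanged.
#'
#' @param volume_fold parenchymal volume fold f (> 0).
#' @return Named numeric vector of expected folds.
#' @export
isotropic_expected_folds <- function(volume_fold) {
  if (volume_fold <= 0) stop("volume fold must be positive")
  lambda <- volume_fold^(1 / 3)
  c(radius = lambda,
    maximal_vessel_length = lambda,
    total_edge_length = lambda,
    total_vascular_volume = volume_fold,
    edge_length_density = lambda^-2,
    vascular_volume_fraction = 1)
}

#' Branching angles of a vascular tree
#'
#' At each bifurcation (epsilon-connectors are transparent: the parent
#' direction is taken from the nearest real ancestor edge, and connector
#' children are resolved to the real edges below them), the deviation
#' angle of each daughter from the parent direction and the inter-daughter
#' angle are extracted from the straight cylinder direction vectors.
#'
#' @param tree a [vascular_tree()].
#' @return Data frame with columns `type` ("deviation" or
#'   "inter_daughter") and `angle` (degrees); empty (with a warning) when
#'   the tree has no bifurcation.
#' @export
branching_angles <- function(tree) {
  e <- tree$edges
  dirs <- edge_directions(tree)
  ch <- children_map(tree)
  # resolve connector children to the real edges below them
  real_children <- function(id) {
    kids <- ch[[as.character(id)]]
    if (is.null(kids)) return(integer(0))
    out <- integer(0)
    for (k in kids) {
      if (e$connector[match(k, e$id)]) out <- c(out, real_children(k))
      else out <- c(out, k)
    }
    out
  }
  ang <- function(u, v) {
    d <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(min(1, max(-1, d))) * 180 / pi
  }
  rows <- list()
  for (i in seq_len(nrow(e))) {
    if (e$connector[i]) next
    kids <- real_children(e$id[i])
    if (length(kids) < 2) next
    pd <- dirs[as.character(e$id[i]), ]
    kd <- dirs[as.character(kids), , drop = FALSE]
    for (k in seq_along(kids))
      rows[[length(rows) + 1L]] <-
        data.frame(type = "deviation", angle = ang(pd, kd[k, ]))
    for (a in seq_len(length(kids) - 1))
      for (b in (a + 1):length(kids))
        rows[[length(rows) + 1L]] <-
          data.frame(type = "inter_daughter", angle = ang(kd[a, ], kd[b, ]))
  }
  if (!length(rows)) {
    warning("tree has no bifurcation; empty angle set")
    return(data.frame(type = character(0), angle = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Histogram-intersection similarity of two angle distributions
#'
#' Both samples are binned over [0, 180] degrees (default 18 bins),
#' normalized to densities summing to one, and compared by
#' sum(min(p_i, q_i)): symmetric, 1 for identical distributions, 0 for
#' disjoint support.
#'
#' @param angles_a,angles_b numeric angle samples (degrees) or the data
#'   frames returned by [branching_angles()] (the `angle` column is used).
#' @param n_bins number of histogram bins over [0, 180].
#' @return Similarity in [0, 1].
#' @export
angle_similarity <- function(angles_a, angles_b, n_bins = 18) {
  get <- function(x) if (is.data.frame(x)) x$angle else as.numeric(x)
  a <- get(angles_a); b <- get(angles_b)
  if (!length(a) || !length(b)) stop("angle samples must be nonempty")
  brks <- seq(0, 180, length.out = n_bins + 1)
  bin <- function(x) {
    h <- tabulate(pmin(n_bins, findInterval(x, brks, rightmost.closed = TRUE)),
                  nbins = n_bins)
    h / sum(h)
  }
  sum(pmin(bin(a), bin(b)))
}

#' Compare observed growth to hypothetical isotropic expansion
#'
#' Computes the parenchymal volume fold f, the visibility threshold theta,
#' the observed per-parameter folds (entire before-tree vs. theta-visible
#' part of the after-tree), the folds expected under isotropic expansion,
#' and a per-parameter and overall compatibility verdict: a parameter is
#' compatible when |observed / expected - 1| <= tolerance. Branching-angle
#' similarity between the two time points is reported alongside.
#'
#' @param tree_before,tree_after [vascular_tree()]s for the two time
#'   points (different specimens are fine; no registration is assumed).
#' @param parenchymal_volume_before,parenchymal_volume_after volumes (ml).
#' @param r_min minimum detectable radius (mm); default: the smallest
#'   non-connector radius in the before-tree.
#' @param tolerance relative compatibility tolerance (default 0.10).
#' @return A `growth_comparison` list.
#' @export
compare_growth <- function(tree_before, tree_after,
                           parenchymal_volume_before,
                           parenchymal_volume_after,
                           r_min = NULL, tolerance = 0.10) {
  stopifnot(parenchymal_volume_before > 0, parenchymal_volume_after > 0)
  if (is.null(r_min)) {
    rr <- tree_before$edges$radius[!tree_before$edges$connector]
    r_min <- min(rr)
  }
  f <- parenchymal_volume_after / parenchymal_volume_before
  vt <- visibility_threshold(f, r_min)
  after_v <- theta_visible_subtree(tree_after, vt$theta)
  if (nrow(after_v$edges) == 0)
    stop("theta-visible remnant of the after-tree is empty")
  observed <- c(
    radius = root_radius(after_v) / root_radius(tree_before),
    maximal_vessel_length =
      maximal_vessel_length(after_v) / maximal_vessel_length(tree_before),
    total_edge_length =
      total_edge_length(after_v) / total_edge_length(tree_before),
    total_vascular_volume =
      total_vascular_volume(after_v) / total_vascular_volume(tree_before),
    edge_length_density =
      edge_length_density(after_v, parenchymal_volume_after) /
      edge_length_density(tree_before, parenchymal_volume_before),
    vascular_volume_fraction =
      vascular_volume_fraction(after_v, parenchymal_volume_after) /
      vascular_volume_fraction(tree_before, parenchymal_volume_before))
  sim <- angle_similarity(branching_angles(tree_before),
                          branching_angles(after_v))
  growth_verdict(observed, f, tolerance,
                 angle_similarity = sim, theta = vt$theta, r_min = r_min)
}

#' @rdname compare_growth
#' @param observed_folds named vector of observed folds (names as in
#'   [isotropic_expected_folds()]; a subset is allowed), e.g. taken from a
#'   published figure rather than from trees.
#' @param volume_fold parenchymal volume fold f.
#' @param angle_similarity optional angle similarity to report alongside.
#' @param theta optional visibility threshold used upstream (mm).
#' @export
growth_verdict <- function(observed_folds, volume_fold, tolerance = 0.10,
                           angle_similarity = NA_real_, theta = NA_real_,
                           r_min = NA_real_) {
  expected <- isotropic_expected_folds(volume_fold)
  use <- intersect(names(expected), names(observed_folds))
  if (!length(use)) stop("no recognizable parameter names in observed_folds")
  obs <- observed_folds[use]
  exp <- expected[use]
  ratio <- obs / exp
  compatible <- abs(ratio - 1) <= tolerance
  structure(list(
    volume_fold = volume_fold,
    lambda = volume_fold^(1 / 3),
    theta = theta, r_min = r_min,
    tolerance = tolerance,
    table = data.frame(parameter = use, observed = unname(obs),
                       expected = unname(exp),
                       ratio = unname(ratio),
                       compatible = unname(compatible)),
    angle_similarity = angle_similarity,
    overall = if (all(compatible)) "compatible" else "incompatible"),
    class = "growth_comparison")
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat(sprintf("<growth_comparison> volume fold f = %.3f (lambda = %.3f), tolerance %.0f%%\n",
              x$volume_fold, x$lambda, 100 * x$tolerance))
  if (is.finite(x$theta))
    cat(sprintf("  visibility threshold theta = %.4f mm (r_min = %.4f mm)\n",
                x$theta, x$r_min))
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-26s observed %6.3f  expected %6.3f  -> %s\n",
                tb$parameter[i], tb$observed[i], tb$expected[i],
                if (tb$compatible[i]) "compatible" else "INCOMPATIBLE"))
  if (is.finite(x$angle_similarity))
    cat(sprintf("  angle similarity %.3f\n", x$angle_similarity))
  cat("  overall:", x$overall, "\n")
  invisible(x)
}
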