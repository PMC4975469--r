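#' Ellipsoidal liver domain helpers
#'
#' @param center,semiaxes ellipsoid center and semi-axes in mm.
#' @return `liver_domain`: a domain list; `ellipsoid_volume_ml`: the
#'   analytic volume (4/3) pi a b c in ml; `in_domain`: logical vector.
#' @export
liver_domain <- function(semiaxes = c(6.2, 4.4, 3.5), center = c(0, 0, 0)) {
  stopifnot(length(semiaxes) == 3, all(semiaxes > 0), length(center) == 3)
  list(center = as.numeric(center), semiaxes = as.numeric(semiaxes))
}

#' @rdname liver_domain
#' @param domain a domain list from [liver_domain()].
#' @export
ellipsoid_volume_ml <- function(domain) {
  4 / 3 * pi * prod(domain$semiaxes) / 1000
}

#' @rdname liver_domain
#' @param points n x 3 matrix of world coordinates (mm).
#' @export
in_domain <- function(points, domain) {
  points <- rbind(points)
  u <- sweep(sweep(points, 2, domain$center, "-"), 2, domain$semiaxes, "/")
  rowSums(u^2) <= 1
}

#' Parameters of the synthetic vascular tree generator
#'
#' Defaults emulate a Microfil-cast venous tree of a mouse liver lobe at
#' the scale reported for regenerating livers: root radius 0.35 mm (the
#' measured normal portal in/outflow radius), minimum radius 0.07 mm (the
#' scan resolution), branch length about six times the local radius, and
#' branching deviation angles around 35 degrees.
#'
#' @param n_tips number of terminal edges (>= 1).
#' @param domain ellipsoidal liver domain, see [liver_domain()].
#' @param root_position world position (mm) where the root cylinder starts.
#' @param root_radius radius of the root cylinder (mm).
#' @param murray_exponent Murray bifurcation exponent m in
#'   r_parent^m = r_child1^m + r_child2^m (default 3).
#' @param length_radius_ratio target ratio of branch length to radius.
#' @param angle_mean,angle_sd mean and SD (degrees) of the truncated-normal
#'   branching deviation angle.
#' @param min_radius smallest admissible radius (mm).
#' @param tip_separation minimum pairwise distance between terminal target
#'   points (mm); default eight times `min_radius`, so terminal branches
#'   stay individually resolvable, as they are in Microfil casts.
#' @param seed integer seed controlling all randomness.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_tips = 64,
                             domain = liver_domain(),
                             root_position = NULL,
                             root_radius = 0.35,
                             murray_exponent = 3,
                             length_radius_ratio = 6,
                             angle_mean = 35,
                             angle_sd = 15,
                             min_radius = 0.07,
                             tip_separation = 8 * min_radius,
                             seed = 1L) {
  if (n_tips < 1) stop("n_tips must be >= 1")
  if (!(root_radius > min_radius && min_radius > 0))
    stop("need root_radius > min_radius > 0")
  if (is.null(root_position))
    root_position <- domain$center - c(0.92 * domain$semiaxes[1], 0, 0)
  if (!in_domain(root_position, domain))
    stop("root_position must lie inside the domain")
  structure(list(n_tips = as.integer(n_tips), domain = domain,
                 root_position = as.numeric(root_position),
                 root_radius = root_radius,
                 murray_exponent = murray_exponent,
                 length_radius_ratio = length_radius_ratio,
                 angle_mean = angle_mean, angle_sd = angle_sd,
                 min_radius = min_radius, tip_separation = tip_separation,
                 seed = as.integer(seed)),
            class = "generator_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) c(1, 0, 0) else v / n
}

# Rotate `from` toward `to` so that the angle between result and `from`
# is `ang` (radians), staying in the plane spanned by the two.
tilt_toward <- function(from, to, ang) {
  from <- unit3(from)
  perp <- to - sum(to * from) * from
  if (sqrt(sum(perp^2)) < 1e-12) {
    # degenerate: pick a deterministic perpendicular
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * from) * from
  }
  unit3(cos(ang) * from + sin(ang) * unit3(perp))
}

#' Generate a synthetic vascular tree
#'
#' Recursive bifurcation toward uniformly sampled target points inside the
#' ellipsoidal liver domain. Targets are split largest-group-first by their
#' principal axis; child radii follow Murray's law with flow proportional
#' to the number of downstream tips, so the Murray residual is zero by
#' construction and radii never increase from root to tip. Branch lengths
#' are `length_radius_ratio` times the radius (with floors that keep
#' successive bifurcations and terminal branches resolvable at scan
#' resolution), shortened when necessary to stay inside the domain;
#' terminal edges aim at their targets, nudged only to keep distinct
#' branches separated by parenchyma.
#'
#' @param params a [generator_params()] list.
#' @return A [vascular_tree()] with `n_tips` terminal edges.
#' @export
generate_tree <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  if (tip_radius_of(p) < p$min_radius)
    stop(sprintf(paste("infeasible geometry: %d tips from root radius %.3g mm",
                       "would need tip radii below min_radius %.3g mm"),
                 p$n_tips, p$root_radius, p$min_radius))
  with_seed(p$seed, {
    targets <- sample_in_ellipsoid(p$n_tips, p$domain,
                                   min_separation = p$tip_separation)
    rows <- list()
    nid <- 0L
    emit <- function(parent, from, to, radius) {
      nid <<- nid + 1L
      rows[[nid]] <<- data.frame(id = nid, parent = parent,
                                 x0 = from[1], y0 = from[2], z0 = from[3],
                                 x1 = to[1], y1 = to[2], z1 = to[3],
                                 radius = radius, lobe = "trunk",
                                 connector = FALSE)
      nid
    }
    # placed segments, for collision avoidance (vessels must not touch:
    # casts of distinct branches are separated by parenchyma)
    placed <- matrix(numeric(0), 0, 7)
    register <- function(from, to, r) placed <<- rbind(placed, c(from, to, r))
    clearance <- function(from, to, r) {
      if (nrow(placed) == 0) return(Inf)
      d <- vapply(seq_len(nrow(placed)), function(k) {
        s <- placed[k, ]
        dd <- seg_seg_dist(from, to, s[1:3], s[4:6]) - r - s[7]
        # contacts at the branch's own junction (parent, sibling, and the
        # immediate neighbourhood of the start point) are anatomical
        near_junction <- seg_seg_dist(from, from, s[1:3], s[4:6]) <
          r + s[7] + 0.05
        if (near_junction) Inf else dd
      }, 0)
      min(d)
    }
    grow <- function(parent_id, origin, direction, radius, targets) {
      n <- nrow(targets)
      if (n == 1) {
        emit(parent_id, origin, targets[1, ], radius)
        register(origin, targets[1, ], radius)
        return(invisible(NULL))
      }
      groups <- split_targets(targets)
      # larger group first: its child carries the larger radius
      ord <- order(vapply(groups, nrow, 1L), decreasing = TRUE)
      min_gap <- 0.25  # mm of parenchyma between distinct branches (>3 voxels)
      for (g in groups[ord]) {
        ng <- nrow(g)
        r_child <- radius * (ng / n)^(1 / p$murray_exponent)
        centroid <- colMeans(g)
        dist_c <- sqrt(sum((centroid - origin)^2))
        to_c <- unit3(centroid - origin)
        if (ng == 1) {
          # terminal branch: aim at the target; enforce a minimum terminal
          # length of 10 radii (short twigs are swallowed by the junction
          # neighbourhood at scan resolution and are not phantom tips),
          # nudging the endpoint if the run would graze an existing branch
          aim <- function(target) {
            d <- unit3(target - origin)
            L <- max(sqrt(sum((target - origin)^2)), 10 * r_child)
            while (L > 0 && !in_domain(origin + L * d, p$domain))
              L <- 0.95 * L
            origin + L * d
          }
          q <- aim(g[1, ])
          if (clearance(origin, q, r_child) <= min_gap) {
            best_q <- q; best_clear <- clearance(origin, q, r_child)
            for (try in 1:12) {
              qq <- aim(g[1, ] + runif(3, -0.45, 0.45))
              cl <- clearance(origin, qq, r_child)
              if (cl > best_clear) { best_clear <- cl; best_q <- qq }
              if (cl > min_gap) break
            }
            q <- best_q
          }
        } else {
          # length floor keeps consecutive bifurcations resolvable
          L <- max(min(p$length_radius_ratio * r_child, 0.7 * dist_c),
                   min(4.5 * r_child, 0.9 * dist_c))
          # draw candidate directions until the branch clears its
          # neighbours; keep the best candidate otherwise
          best_q <- NULL; best_clear <- -Inf
          for (try in 1:12) {
            # floor at 20 degrees so sibling branches separate promptly
            ang <- rtruncnorm1(p$angle_mean, p$angle_sd, 20, 80) * pi / 180
            d <- tilt_toward(direction, to_c, ang)
            q <- origin + L * d
            if (!in_domain(q, p$domain)) q <- origin + L * to_c
            cl <- clearance(origin, q, r_child)
            if (cl > best_clear) { best_clear <- cl; best_q <- q }
            if (cl > min_gap) break
          }
          q <- best_q
        }
        eid <- emit(parent_id, origin, q, r_child)
        register(origin, q, r_child)
        if (ng > 1) grow(eid, q, unit3(q - origin), r_child, g)
      }
      invisible(NULL)
    }
    # after generation, relax any residual branch-branch contacts:
    # distinct vessels are separated by parenchyma in real casts
    # (resolve_collisions below)
    # trunk: from the root position toward the cloud of targets
    centroid <- colMeans(targets)
    d0 <- unit3(centroid - p$root_position)
    if (p$n_tips == 1) {
      root <- emit(NA_integer_, p$root_position, targets[1, ], p$root_radius)
    } else {
      L0 <- min(p$length_radius_ratio * p$root_radius,
                0.5 * sqrt(sum((centroid - p$root_position)^2)))
      q0 <- p$root_position + L0 * d0
      root <- emit(NA_integer_, p$root_position, q0, p$root_radius)
      grow(root, q0, d0, p$root_radius, targets)
    }
    tr <- vascular_tree(do.call(rbind, rows), domain = p$domain)
    tr <- resolve_collisions(tr, gap = 0.25)
    tr <- enforce_sibling_angles(tr, min_angle = 30)
    resolve_collisions(tr, gap = 0.25)
  })
}

# Two branches leaving one bifurcation must diverge by a minimum angle,
# or the narrower one runs inside its sibling and the pair is a single
# vessel for all practical (and imaging) purposes. Rotates the
# smaller-radius sibling's endpoint away from the other within their
# common plane; children of the moved edge follow their start point.
enforce_sibling_angles <- function(tree, min_angle = 30) {
  e <- tree$edges
  ch <- children_map(tree)
  amin <- min_angle * pi / 180
  for (pid in names(ch)) {
    kids <- ch[[pid]]
    if (length(kids) != 2) next
    i <- match(kids[1], e$id); j <- match(kids[2], e$id)
    # keep the larger-radius sibling fixed
    if (e$radius[j] > e$radius[i]) { tmp <- i; i <- j; j <- tmp }
    org <- c(e$x0[i], e$y0[i], e$z0[i])
    d1 <- c(e$x1[i], e$y1[i], e$z1[i]) - org
    d2 <- c(e$x1[j], e$y1[j], e$z1[j]) - org
    L2 <- sqrt(sum(d2^2))
    u1 <- unit3(d1); u2 <- unit3(d2)
    ang <- acos(min(1, max(-1, sum(u1 * u2))))
    if (ang >= amin) next
    # rotate u2 away from u1 to min_angle + 2 degrees
    target <- amin + 2 * pi / 180
    perp <- u2 - sum(u2 * u1) * u1
    if (sqrt(sum(perp^2)) < 1e-9) {
      perp <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * u1) * u1
    }
    perp <- unit3(perp)
    is_tip <- !e$id[j] %in% e$parent
    for (fac in c(1, 0.85, 0.7)) {
      if (is_tip && fac * L2 < 9 * e$radius[j]) break
      q <- org + fac * L2 * (cos(target) * u1 + sin(target) * perp)
      if (is.null(tree$domain) || in_domain(q, tree$domain)) {
        moved <- match(e$id[j], e$id)
        e$x1[moved] <- q[1]; e$y1[moved] <- q[2]; e$z1[moved] <- q[3]
        grand <- which(e$parent == e$id[j])
        e$x0[grand] <- q[1]; e$y0[grand] <- q[2]; e$z0[grand] <- q[3]
        break
      }
    }
  }
  vascular_tree(e, domain = tree$domain, validate = FALSE)
}

# Move tree nodes (an edge's end point together with its children's start
# points) away from non-adjacent branches until every pair of distinct
# vessels is separated by at least `gap` mm of parenchyma. The node moved
# for each conflict is the one closest to the contact point — that is the
# node with leverage over it. Uses the RNG (call under with_seed).
resolve_collisions <- function(tree, gap = 0.25, max_passes = 60) {
  e <- tree$edges
  n <- nrow(e)
  if (n < 2) return(tree)
  P0 <- as.matrix(e[, c("x0", "y0", "z0")])
  P1 <- as.matrix(e[, c("x1", "y1", "z1")])
  r <- e$radius
  # adjacency: edges sharing an endpoint (junction contacts are anatomical)
  shares <- function(i, j) {
    min(sum((P0[i, ] - P0[j, ])^2), sum((P0[i, ] - P1[j, ])^2),
        sum((P1[i, ] - P0[j, ])^2), sum((P1[i, ] - P1[j, ])^2)) < 1e-16
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <- shares(i, j)
  pair_clear <- function(i, j)
    seg_seg_dist(P0[i, ], P1[i, ], P0[j, ], P1[j, ]) - r[i] - r[j]
  conflicts <- function() {
    out <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (!adj[i, j] && pair_clear(i, j) < gap) out <- rbind(out, c(i, j))
    out
  }
  kids_of <- lapply(seq_len(n), function(i) which(e$parent == e$id[i]))
  parent_row <- match(e$parent, e$id)
  # worst clearance among pairs involving the star of node `m` (= end of
  # edge m plus its children)
  star_clear <- function(m) {
    grp <- c(m, kids_of[[m]])
    worst <- Inf
    for (a in grp) for (j in seq_len(n))
      if (!(j %in% grp) && !adj[a, j])
        worst <- min(worst, pair_clear(a, j))
    worst
  }
  # closest point of approach between edges i and j, as position on i
  contact_point <- function(i, j) {
    d1 <- P1[i, ] - P0[i, ]; d2 <- P1[j, ] - P0[j, ]
    # coarse parametric search is plenty here
    ts <- seq(0, 1, length.out = 21)
    besti <- 0; bestd <- Inf
    for (s in ts) {
      pt <- P0[i, ] + s * d1
      dd <- seg_seg_dist(pt, pt, P0[j, ], P1[j, ])
      if (dd < bestd) { bestd <- dd; besti <- s }
    }
    P0[i, ] + besti * d1
  }
  dom <- tree$domain
  is_tip_edge <- vapply(seq_len(n), function(i) length(kids_of[[i]]) == 0, TRUE)
  move_node <- function(m) {
    base <- star_clear(m)
    best <- base; best_p <- NULL
    old <- P1[m, ]
    for (try in 1:30) {
      cand <- old + runif(3, -1, 1) * (0.1 + 0.4 * (try / 30))
      if (!is.null(dom) && !in_domain(cand, dom)) next
      # terminal branches must stay long enough to survive skeleton-end
      # retraction as distinct tips
      if (is_tip_edge[m] && sqrt(sum((cand - P0[m, ])^2)) < 9 * r[m]) next
      P1[m, ] <<- cand
      for (k in kids_of[[m]]) P0[k, ] <<- cand
      sc <- star_clear(m)
      if (sc > best) { best <- sc; best_p <- cand }
      if (sc >= gap) break
    }
    P1[m, ] <<- old
    for (k in kids_of[[m]]) P0[k, ] <<- old
    if (!is.null(best_p)) {
      P1[m, ] <<- best_p
      for (k in kids_of[[m]]) P0[k, ] <<- best_p
      TRUE
    } else FALSE
  }
  for (pass in seq_len(max_passes)) {
    cf <- conflicts()
    if (is.null(cf)) break
    moved <- FALSE
    for (row in seq_len(nrow(cf))) {
      i <- cf[row, 1]; j <- cf[row, 2]
      cp <- contact_point(i, j)
      # candidate nodes: ends of i, j, and their parents (= their starts)
      cand_nodes <- unique(stats::na.omit(c(i, j, parent_row[i], parent_row[j])))
      dists <- vapply(cand_nodes, function(m) sum((P1[m, ] - cp)^2), 0)
      for (m in cand_nodes[order(dists)]) {
        if (move_node(m)) { moved <- TRUE; break }
      }
    }
    if (!moved) break
  }
  e$x0 <- P0[, 1]; e$y0 <- P0[, 2]; e$z0 <- P0[, 3]
  e$x1 <- P1[, 1]; e$y1 <- P1[, 2]; e$z1 <- P1[, 3]
  vascular_tree(e, domain = tree$domain, validate = FALSE)
}

tip_radius_of <- function(p) p$root_radius * (1 / p$n_tips)^(1 / p$murray_exponent)

sample_in_ellipsoid <- function(n, domain, min_separation = 0) {
  out <- matrix(0, n, 3)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("infeasible geometry: cannot place ", n, " tips ",
           min_separation, " mm apart inside the domain")
    cand <- runif(3, -1, 1)
    if (sum(cand^2) > 1) next
    pt <- domain$center + cand * domain$semiaxes
    if (min_separation > 0 && got > 0) {
      d2 <- rowSums(sweep(out[seq_len(got), , drop = FALSE], 2, pt, "-")^2)
      if (min(d2) < min_separation^2) next
    }
    got <- got + 1L
    out[got, ] <- pt
  }
  out
}

# Split target points into two balanced groups by their principal axis.
split_targets <- function(targets) {
  ctr <- colMeans(targets)
  x <- sweep(targets, 2, ctr, "-")
  if (nrow(targets) == 2) {
    return(list(targets[1, , drop = FALSE], targets[2, , drop = FALSE]))
  }
  ax <- eigen(crossprod(x), symmetric = TRUE)$vectors[, 1]
  proj <- as.numeric(x %*% ax)
  ord <- order(proj, seq_along(proj))  # deterministic tie-break
  half <- floor(length(proj) / 2)
  list(targets[ord[seq_len(half)], , drop = FALSE],
       targets[ord[(half + 1):length(proj)], , drop = FALSE])
}

#' Growth transform specification
#'
#' @param mode one of `"isotropic"`, `"anisotropic"`, `"dilation"`,
#'   `"outgrowth"`, `"composite"`.
#' @param lambda scale factor for isotropic expansion (lengths and radii
#'   multiply by lambda; volumes by lambda^3).
#' @param lambda_xyz per-axis factors for anisotropic scaling.
#' @param radius_factor factor for radius-only dilation.
#' @param outgrowth_tips number of new terminal bifurcations to append.
#' @param seed seed for the stochastic outgrowth placement.
#' @param steps list of growth_spec objects for `mode = "composite"`,
#'   applied in order.
#' @return A `growth_spec` list.
#' @export
growth_spec <- function(mode = c("isotropic", "anisotropic", "dilation",
                                 "outgrowth", "composite"),
                        lambda = 1, lambda_xyz = c(1, 1, 1),
                        radius_factor = 1, outgrowth_tips = 0,
                        seed = NULL, steps = NULL) {
  mode <- match.arg(mode)
  if (lambda <= 0 || any(lambda_xyz <= 0) || radius_factor <= 0)
    stop("all growth factors must be positive")
  if (mode == "composite" && (is.null(steps) || !length(steps)))
    stop("composite growth needs a non-empty `steps` list")
  structure(list(mode = mode, lambda = lambda,
                 lambda_xyz = as.numeric(lambda_xyz),
                 radius_factor = radius_factor,
                 outgrowth_tips = as.integer(outgrowth_tips),
                 seed = seed, steps = steps),
            class = "growth_spec")
}

#' Apply a growth transform to a vascular tree
#'
#' Isotropic expansion scales all endpoint coordinates by `lambda` about
#' the domain center and multiplies radii by `lambda`. Dilation scales
#' radii only. Anisotropic scaling applies per-axis factors to coordinates
#' and the mean factor to radii. Outgrowth appends new terminal
#' bifurcations (two child edges with radii in (0.25, 0.5] of the parent's)
#' at randomly chosen tips, emulating the out-branching of smaller vessels
#' that cross the visibility threshold during regeneration.
#'
#' @param tree a [vascular_tree()].
#' @param spec a [growth_spec()].
#' @param center scaling center; defaults to the tree's domain center.
#' @return The transformed [vascular_tree()].
#' @export
apply_growth <- function(tree, spec, center = NULL) {
  stopifnot(inherits(tree, "vascular_tree"), inherits(spec, "growth_spec"))
  if (spec$mode == "composite") {
    for (s in spec$steps) tree <- apply_growth(tree, s, center = center)
    return(tree)
  }
  if (is.null(center))
    center <- if (!is.null(tree$domain)) tree$domain$center else c(0, 0, 0)
  e <- tree$edges
  scale_pts <- function(fac) {
    for (ax in 1:3) {
      c0 <- c("x0", "y0", "z0")[ax]; c1 <- c("x1", "y1", "z1")[ax]
      e[[c0]] <<- center[ax] + (e[[c0]] - center[ax]) * fac[ax]
      e[[c1]] <<- center[ax] + (e[[c1]] - center[ax]) * fac[ax]
    }
  }
  if (spec$mode == "isotropic") {
    if (spec$lambda == 1) return(tree)
    scale_pts(rep(spec$lambda, 3))
    e$radius <- e$radius * spec$lambda
    dom <- tree$domain
    if (!is.null(dom)) dom$semiaxes <- dom$semiaxes * spec$lambda
    return(vascular_tree(e, domain = dom, validate = FALSE))
  }
  if (spec$mode == "anisotropic") {
    scale_pts(spec$lambda_xyz)
    e$radius <- e$radius * mean(spec$lambda_xyz)
    dom <- tree$domain
    if (!is.null(dom)) dom$semiaxes <- dom$semiaxes * spec$lambda_xyz
    return(vascular_tree(e, domain = dom, validate = FALSE))
  }
  if (spec$mode == "dilation") {
    if (spec$radius_factor == 1) return(tree)
    e$radius <- e$radius * spec$radius_factor
    return(vascular_tree(e, domain = tree$domain, validate = FALSE))
  }
  # outgrowth
  with_seed(spec$seed, {
    tr <- vascular_tree(e, domain = tree$domain, validate = FALSE)
    tips <- tip_ids(tr)
    n_new <- min(spec$outgrowth_tips, length(tips))
    chosen <- sample(tips, n_new)
    dirs <- edge_directions(tr)
    lens <- edge_lengths(tr)
    nid <- max(e$id)
    for (tid in chosen) {
      i <- which(e$id == tid)
      from <- c(e$x1[i], e$y1[i], e$z1[i])
      d0 <- dirs[as.character(tid), ]
      for (side in c(-1, 1)) {
        r_new <- e$radius[i] * runif(1, 0.25, 0.5)
        ang <- rtruncnorm1(35, 15, 5, 80) * pi / 180
        perp <- unit3(if (abs(d0[1]) < 0.9) pracma_cross(d0, c(1, 0, 0))
                      else pracma_cross(d0, c(0, 1, 0)))
        d_new <- unit3(cos(ang) * d0 + side * sin(ang) * perp)
        L <- max(lens[as.character(tid)] * 0.5, 4 * r_new)
        if (!is.null(tree$domain)) {
          # keep new endpoints inside the liver domain
          while (L > 8 * .Machine$double.eps &&
                 !in_domain(from + L * d_new, tree$domain)) L <- L / 2
          if (!in_domain(from + L * d_new, tree$domain))
            d_new <- unit3(tree$domain$center - from)
        }
        nid <- nid + 1L
        e <- rbind(e, data.frame(id = nid, parent = tid,
                                 x0 = from[1], y0 = from[2], z0 = from[3],
                                 x1 = from[1] + L * d_new[1],
                                 y1 = from[2] + L * d_new[2],
                                 z1 = from[3] + L * d_new[3],
                                 radius = r_new, lobe = e$lobe[i],
                                 connector = FALSE))
      }
    }
    vascular_tree(e, domain = tree$domain, validate = FALSE)
  })
}

# minimum distance between two 3D segments
seg_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- .Machine$double.eps
  if (a <= eps && e <= eps) return(sqrt(sum(r^2)))
  if (a <= eps) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c0 <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(max(-c0 / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > eps) min(max((b * f - c0 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c0 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c0) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Voxelize a vascular tree into a micro-CT-like phantom volume
#'
#' Produces a scalar volume on a grid covering the ellipsoidal liver domain
#' plus a margin: voxels whose center falls inside some vessel cylinder get
#' `vessel_intensity`, other voxels inside the ellipsoid get
#' `tissue_intensity`, the rest `background_intensity`; optional i.i.d.
#' Gaussian noise is added. The default spacing of 0.07 mm matches the
#' isotropic 70 um resolution of the micro-CT protocol being emulated.
#'
#' @param tree a [vascular_tree()] whose endpoints lie inside `domain`.
#' @param spacing voxel edge length (mm).
#' @param domain ellipsoidal liver domain; defaults to the tree's.
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param vessel_intensity,tissue_intensity,background_intensity intensities.
#' @param margin grid margin around the domain (mm).
#' @param seed seed for the noise.
#' @return A list with components `volume` ([voxel_volume()]), `liver`
#'   (ellipsoid-plus-vessel [binary_mask()]) and `vessel_truth`
#'   (noise-free vessel occupancy [binary_mask()]).
#' @export
voxelize <- function(tree, spacing = 0.07, domain = NULL, noise_sd = 50,
                     vessel_intensity = 1000, tissue_intensity = 100,
                     background_intensity = 0, margin = 0.5, seed = NULL) {
  stopifnot(inherits(tree, "vascular_tree"), spacing > 0)
  if (is.null(domain)) domain <- tree$domain
  if (is.null(domain)) stop("no domain: pass `domain` or generate the tree with one")
  e <- tree$edges
  pts <- rbind(as.matrix(e[, c("x0", "y0", "z0")]),
               as.matrix(e[, c("x1", "y1", "z1")]))
  if (!all(in_domain(pts, domain)))
    stop("tree endpoint(s) outside the liver domain")
  lo <- domain$center - domain$semiaxes - margin
  hi <- domain$center + domain$semiaxes + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  origin <- lo
  seg <- cbind(e$x0, e$y0, e$z0, e$x1, e$y1, e$z1, e$radius)
  vessel <- voxelize_cylinders_cpp(seg, dims, origin, spacing)
  if (!any(vessel))
    stop("spacing too coarse: no voxel center falls inside any vessel")
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing)
  u1 <- (ax[[1]] - domain$center[1])^2 / domain$semiaxes[1]^2
  u2 <- (ax[[2]] - domain$center[2])^2 / domain$semiaxes[2]^2
  u3 <- (ax[[3]] - domain$center[3])^2 / domain$semiaxes[3]^2
  ell <- outer(outer(u1, u2, "+"), u3, "+") <= 1
  liver <- ell | vessel
  vals <- array(background_intensity, dims)
  vals[ell] <- tissue_intensity
  vals[vessel] <- vessel_intensity
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, array(rnorm(prod(dims), 0, noise_sd), dims))
  list(volume = voxel_volume(vals, spacing, origin),
       liver = binary_mask(liver, spacing, origin),
       vessel_truth = binary_mask(array(vessel, dims), spacing, origin))
}

#' Paired before/after phantom study
#'
#' Generates a ground-truth tree, applies a growth transform, and (by
#' default) voxelizes both states, yielding the paired
#' "after virtual resection" / "POD 7" specimens that the regeneration
#' analysis consumes, with the generating truth recorded.
#'
#' @param params a [generator_params()].
#' @param spec a [growth_spec()] describing the growth between time points.
#' @param spacing voxel spacing (mm) for the phantom volumes.
#' @param rasterize voxelize both time points (default TRUE); set FALSE for
#'   ground-truth-tree analyses that need no volumes.
#' @param ... further arguments to [voxelize()].
#' @return A `phantom_study` list: `tree_before`, `tree_after`,
#'   `volume_before`, `volume_after`, `liver_mask_before`,
#'   `liver_mask_after`, `vessel_truth_before`, `vessel_truth_after`,
#'   `truth` (the growth spec), `params`.
#' @export
make_phantom_study <- function(params, spec, spacing = 0.07,
                               rasterize = TRUE, ...) {
  tree_before <- generate_tree(params)
  tree_after <- apply_growth(tree_before, spec)
  out <- list(tree_before = tree_before, tree_after = tree_after,
              truth = spec, params = params)
  if (rasterize) {
    noise_seed <- params$seed + 1000003L
    vb <- voxelize(tree_before, spacing = spacing, seed = noise_seed, ...)
    va <- voxelize(tree_after, spacing = spacing, seed = noise_seed, ...)
    out$volume_before <- vb$volume
    out$volume_after <- va$volume
    out$liver_mask_before <- vb$liver
    out$liver_mask_after <- va$liver
    out$vessel_truth_before <- vb$vessel_truth
    out$vessel_truth_after <- va$vessel_truth
  }
  structure(out, class = "phantom_study")
}
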