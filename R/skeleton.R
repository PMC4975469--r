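#' 3D skeletonization of a vessel mask
#'
#' Sequential six-subiteration border thinning using the (26, 6)
#' simple-point characterization (a voxel is deletable iff removing it
#' changes neither object nor background topology) with endpoint
#' preservation, yielding a one-voxel-wide 26-connected curve skeleton
#' that preserves the topology of every mask component.
#'
#' @param mask a nonempty vessel [binary_mask()].
#' @return A [binary_mask()] holding the centerline voxel set.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("cannot skeletonize an empty mask")
  dims <- dim(mask$values)
  sk <- thin_skeleton_cpp(mask$values, dims)
  binary_mask(array(sk, dims), mask$spacing, mask$origin)
}

skeleton_voxels <- function(skeleton) {
  which(skeleton$values, arr.ind = TRUE)
}

#' Centerline radius estimation by distance transform
#'
#' The radius at a centerline point is its Euclidean distance (mm) to the
#' nearest background voxel center, i.e. the maximal inscribed sphere
#' radius. Structures thinner than the voxel size cannot be measured;
#' such points are flagged below-resolution and reported as spacing / 2.
#'
#' @param mask the vessel [binary_mask()] the centerline came from.
#' @param skeleton centerline [binary_mask()] (subset of `mask`), or an
#'   n x 3 matrix of 1-based voxel indices into `mask`.
#' @return Numeric vector of radii (mm), one per centerline voxel in
#'   linear-index order, with attributes `points` (voxel index matrix) and
#'   `below_resolution` (logical).
#' @export
estimate_radii <- function(mask, skeleton) {
  stopifnot(inherits(mask, "binary_mask"))
  pts <- if (inherits(skeleton, "binary_mask")) skeleton_voxels(skeleton)
         else rbind(skeleton)
  dims <- dim(mask$values)
  linear <- pts[, 1] + (pts[, 2] - 1) * dims[1] +
    (pts[, 3] - 1) * dims[1] * dims[2]
  if (any(!mask$values[linear]))
    stop("centerline point(s) outside the vessel mask")
  d2 <- edt_squared_cpp(mask$values, dims)
  r_vox <- sqrt(d2[linear])
  # a 1-voxel-wide line has unit distance to background: anything at or
  # below that is unresolvable
  below <- r_vox <= 1
  r <- r_vox * mask$spacing
  r[below] <- mask$spacing / 2
  attr(r, "points") <- pts
  attr(r, "below_resolution") <- below
  r
}

new_vascular_graph <- function(nodes, edges, root, spacing) {
  structure(list(nodes = nodes, edges = edges, root = root,
                 spacing = spacing),
            class = "vascular_graph")
}

#' @export
print.vascular_graph <- function(x, ...) {
  cat(sprintf("<vascular_graph> %d nodes, %d edges, root node %d\n",
              nrow(x$nodes), length(x$edges), x$root))
  invisible(x)
}

#' Build a centerline graph from a skeleton
#'
#' Junction voxels (three or more skeleton neighbors) are merged into
#' nodes at the centroid of each 26-connected junction cluster; maximal
#' junction-free skeleton runs become edges carrying their ordered
#' centerline polylines and per-point radii. Components not reachable from
#' the root are discarded (with a message). Loops, which can arise from
#' imaging artifacts, are broken by removing the non-bridge edge with the
#' smallest mean radius. Optionally, short terminal spurs (a known thinning
#' artifact on thick vessels) are pruned, and terminal centerlines are
#' extended into the vessel end caps along their final direction (medial
#' axes retract from ends by about one local radius).
#'
#' @param skeleton centerline [binary_mask()] from [skeletonize()].
#' @param radii per-point radii from [estimate_radii()] (same voxel order).
#' @param root_point world coordinates (mm) of the vascular root; must lie
#'   within a few voxels of a skeleton endpoint.
#' @param mask the original vessel mask (enables tip extension).
#' @param prune_spurs prune terminal spurs shorter than
#'   `spur_factor * local radius` (default TRUE).
#' @param spur_factor spur length threshold in units of the junction-side
#'   radius (default 3.5).
#' @return A `vascular_graph`: `nodes` (data frame id, x, y, z in mm,
#'   degree), `edges` (list of id, from, to, path matrix (mm), radii),
#'   `root` node id.
#' @export
build_graph <- function(skeleton, radii, root_point, mask = NULL,
                        prune_spurs = TRUE, spur_factor = 3.5) {
  stopifnot(inherits(skeleton, "binary_mask"))
  dims <- dim(skeleton$values)
  sp <- skeleton$spacing
  vox <- skeleton_voxels(skeleton)
  n <- nrow(vox)
  if (n == 0) stop("empty skeleton")
  stopifnot(length(radii) == n)

  linear <- vox[, 1] + (vox[, 2] - 1) * dims[1] + (vox[, 3] - 1) * dims[1] * dims[2]
  # adjacency among skeleton voxels (26-connectivity)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (o in seq_len(nrow(offs))) {
    ni <- vox[, 1] + offs[o, 1]; nj <- vox[, 2] + offs[o, 2]; nk <- vox[, 3] + offs[o, 3]
    okb <- ni >= 1 & nj >= 1 & nk >= 1 & ni <= dims[1] & nj <= dims[2] & nk <= dims[3]
    nlin <- ni[okb] + (nj[okb] - 1) * dims[1] + (nk[okb] - 1) * dims[1] * dims[2]
    hit <- match(nlin, linear)
    src <- which(okb)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    keep <- src < dst
    pairs_a <- c(pairs_a, src[keep]); pairs_b <- c(pairs_b, dst[keep])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(pairs_a))
    g <- igraph::add_edges(g, rbind(pairs_a, pairs_b))
  deg <- igraph::degree(g)

  world <- voxel_to_world(skeleton, vox)
  is_junction <- deg >= 3

  nodes_pos <- list(); node_kind <- character(0)
  cluster_of <- rep(NA_integer_, n)
  if (any(is_junction)) {
    sub <- igraph::induced_subgraph(g, which(is_junction))
    comp <- igraph::components(sub)$membership
    jidx <- which(is_junction)
    # deterministic cluster numbering by smallest member linear index
    first_lin <- tapply(linear[jidx], comp, min)
    relab <- as.integer(factor(first_lin[comp], levels = sort(unique(first_lin))))
    for (cl in sort(unique(relab))) {
      members <- jidx[relab == cl]
      # radius-weighted centroid: keeps the node on the axis of the
      # thickest vessel through the junction instead of drifting into
      # side branches
      w <- radii[members]^2
      nodes_pos[[length(nodes_pos) + 1L]] <-
        colSums(world[members, , drop = FALSE] * w) / sum(w)
      node_kind <- c(node_kind, "junction")
      cluster_of[members] <- length(nodes_pos)
    }
  }

  edges <- list()
  add_edge <- function(from, to, path, rr) {
    edges[[length(edges) + 1L]] <<- list(id = length(edges) + 1L,
                                         from = from, to = to,
                                         path = smooth_path(path), radii = rr)
  }
  new_tip_node <- function(pos) {
    nodes_pos[[length(nodes_pos) + 1L]] <<- pos
    node_kind <<- c(node_kind, "tip")
    length(nodes_pos)
  }

  # runs: components among non-junction voxels
  nonj <- which(!is_junction)
  if (length(nonj)) {
    sub <- igraph::induced_subgraph(g, nonj)
    comp <- igraph::components(sub)$membership
    for (cl in seq_len(max(comp))) {
      members <- nonj[comp == cl]
      subg <- igraph::induced_subgraph(g, members)
      dsub <- igraph::degree(subg)
      ends <- which(dsub <= 1)
      if (length(ends) == 0) ends <- 1L  # isolated cycle: arbitrary cut
      ordv <- as.integer(igraph::dfs(subg, root = ends[1])$order)
      run <- members[ordv]
      # junction clusters adjacent to each end of the run
      attach_clusters <- function(vid) {
        nb <- as.integer(igraph::neighbors(g, vid))
        sort(unique(cluster_of[nb[is_junction[nb]]]))
      }
      cls_head <- attach_clusters(run[1])
      cls_tail <- attach_clusters(run[length(run)])
      c_head <- if (length(cls_head)) cls_head[1] else NA_integer_
      if (length(run) == 1 && length(cls_head) > 1) {
        c_tail <- cls_head[2]  # one voxel bridging two junction clusters
      } else {
        c_tail <- if (length(cls_tail)) cls_tail[1] else NA_integer_
      }
      path <- world[run, , drop = FALSE]
      rr <- radii[run]
      if (!is.na(c_head)) {
        path <- rbind(nodes_pos[[c_head]], path); rr <- c(rr[1], rr)
        from <- c_head
      } else {
        from <- new_tip_node(world[run[1], ])
      }
      if (!is.na(c_tail) && !(length(run) == 1 && !is.na(c_head) && c_tail == c_head)) {
        path <- rbind(path, nodes_pos[[c_tail]]); rr <- c(rr, rr[length(rr)])
        to <- c_tail
      } else if (!is.na(c_tail)) {
        # single voxel attached to one cluster on both logical ends
        to <- new_tip_node(world[run[length(run)], ])
      } else {
        to <- new_tip_node(world[run[length(run)], ])
      }
      add_edge(from, to, path, rr)
    }
  }

  # direct junction-cluster / junction-cluster adjacencies
  if (length(pairs_a)) {
    jj <- is_junction[pairs_a] & is_junction[pairs_b] &
      cluster_of[pairs_a] != cluster_of[pairs_b]
    if (any(jj)) {
      seen <- character(0)
      for (k in which(jj)) {
        ca <- cluster_of[pairs_a[k]]; cb <- cluster_of[pairs_b[k]]
        key <- paste(min(ca, cb), max(ca, cb))
        if (key %in% seen) next
        seen <- c(seen, key)
        pa <- nodes_pos[[ca]]; pb <- nodes_pos[[cb]]
        rmean <- mean(radii[c(pairs_a[k], pairs_b[k])])
        add_edge(ca, cb, rbind(pa, pb), c(rmean, rmean))
      }
    }
  }

  nodes <- data.frame(id = seq_along(nodes_pos),
                      x = vapply(nodes_pos, `[`, 0, 1),
                      y = vapply(nodes_pos, `[`, 0, 2),
                      z = vapply(nodes_pos, `[`, 0, 3),
                      kind = node_kind)

  gr <- new_vascular_graph(nodes, edges, root = NA_integer_, spacing = sp)
  gr <- graph_break_loops(gr)

  # root: nearest node to root_point (prefer tips), within 3 voxels
  dd <- sqrt((nodes$x - root_point[1])^2 + (nodes$y - root_point[2])^2 +
               (nodes$z - root_point[3])^2)
  pref <- dd + ifelse(nodes$kind == "tip", 0, 2 * sp)
  # medial skeletons retract from an open vessel end by about one local
  # radius, so allow a search radius of a dozen voxels
  cand <- which(dd <= 12 * sp)
  if (length(cand) == 0)
    stop("no skeleton endpoint near root_point (nearest node ",
         signif(min(dd), 3), " mm away)")
  gr$root <- cand[which.min(pref[cand])]

  gr <- graph_keep_root_component(gr)
  if (prune_spurs) gr <- graph_prune_spurs(gr, spur_factor = spur_factor)
  if (!is.null(mask)) gr <- graph_extend_tips(gr, mask)
  gr$nodes$degree <- graph_degrees(gr)
  gr
}

graph_degrees <- function(gr) {
  deg <- integer(nrow(gr$nodes))
  for (e in gr$edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  deg
}

graph_igraph <- function(gr) {
  igraph::make_graph(edges = as.integer(rbind(
    vapply(gr$edges, `[[`, 0L, "from"),
    vapply(gr$edges, `[[`, 0L, "to"))),
    n = nrow(gr$nodes), directed = FALSE)
}

# Laplacian smoothing of a centerline polyline (endpoints fixed): removes
# the zigzag of a digitized curve, which otherwise inflates centerline
# length estimates by up to ~12%, and relaxes the residual bending that
# digital medial axes show next to junctions
smooth_path <- function(path, iterations = 8) {
  n <- nrow(path)
  if (n < 3) return(path)
  for (it in seq_len(iterations)) {
    interior <- 2:(n - 1)
    path[interior, ] <- (path[interior - 1, , drop = FALSE] +
                           path[interior, , drop = FALSE] +
                           path[interior + 1, , drop = FALSE]) / 3
  }
  path
}

path_length_mm <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums((path[-1, , drop = FALSE] -
                      path[-nrow(path), , drop = FALSE])^2)))
}

graph_break_loops <- function(gr) {
  repeat {
    if (!length(gr$edges)) return(gr)
    ig <- graph_igraph(gr)
    nv <- igraph::vcount(ig)
    ncomp <- igraph::components(ig)$no
    if (igraph::ecount(ig) <= nv - ncomp) return(gr)  # forest: done
    bridges <- igraph::bridges(ig)
    nonbridge <- setdiff(seq_along(gr$edges), as.integer(bridges))
    rmean <- vapply(gr$edges[nonbridge], function(e) mean(e$radii), 0)
    drop <- nonbridge[which.min(rmean)]
    message("breaking skeleton loop: removing edge with mean radius ",
            signif(min(rmean), 3), " mm")
    gr$edges <- gr$edges[-drop]
    for (k in seq_along(gr$edges)) gr$edges[[k]]$id <- k
  }
}

graph_keep_root_component <- function(gr) {
  ig <- graph_igraph(gr)
  comp <- igraph::components(ig)$membership
  keep_nodes <- comp == comp[gr$root]
  if (all(keep_nodes)) return(gr)
  n_drop <- sum(!keep_nodes)
  message("discarding ", n_drop,
          " skeleton node(s) not reachable from the root")
  graph_subset_nodes(gr, which(keep_nodes))
}

graph_subset_nodes <- function(gr, keep) {
  remap <- rep(NA_integer_, nrow(gr$nodes))
  remap[keep] <- seq_along(keep)
  edges <- Filter(function(e) !is.na(remap[e$from]) && !is.na(remap[e$to]),
                  gr$edges)
  edges <- lapply(seq_along(edges), function(k) {
    e <- edges[[k]]
    e$id <- k; e$from <- remap[e$from]; e$to <- remap[e$to]
    e
  })
  nodes <- gr$nodes[keep, , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL
  new_vascular_graph(nodes, edges, root = remap[gr$root], spacing = gr$spacing)
}

# Remove terminal spur edges shorter than spur_factor * junction radius,
# then re-merge any degree-2 interior nodes so runs stay maximal.
graph_prune_spurs <- function(gr, spur_factor = 3.5) {
  repeat {
    deg <- graph_degrees(gr)
    dropped <- FALSE
    for (k in seq_along(gr$edges)) {
      e <- gr$edges[[k]]
      tip_end <- if (deg[e$to] == 1 && e$to != gr$root) "to"
                 else if (deg[e$from] == 1 && e$from != gr$root) "from"
                 else next
      other <- if (tip_end == "to") e$from else e$to
      if (deg[other] < 3) next  # do not prune isolated chains
      # thinning spurs protrude at most a few junction radii from the
      # junction blob; resolvable terminal branches are much longer
      r_jct <- if (tip_end == "to") e$radii[1] else e$radii[length(e$radii)]
      len <- path_length_mm(e$path)
      # below-resolution twigs (noise voxels riding on a vessel wall) are
      # never reportable branches
      noise_twig <- mean(e$radii) < 1.5 * gr$spacing && len < 6 * gr$spacing
      if (noise_twig || len < max(spur_factor * r_jct, 2 * gr$spacing)) {
        gr$edges <- gr$edges[-k]
        for (kk in seq_along(gr$edges)) gr$edges[[kk]]$id <- kk
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  # drop now-isolated tip nodes and merge degree-2 pass-through nodes
  gr <- graph_drop_isolated(gr)
  graph_merge_degree2(gr)
}

graph_drop_isolated <- function(gr) {
  deg <- graph_degrees(gr)
  keep <- which(deg > 0 | gr$nodes$id == gr$root)
  if (length(keep) == nrow(gr$nodes)) gr else graph_subset_nodes(gr, keep)
}

graph_merge_degree2 <- function(gr) {
  repeat {
    deg <- graph_degrees(gr)
    mid <- which(deg == 2 & gr$nodes$id != gr$root)
    if (!length(mid)) return(gr)
    v <- mid[1]
    inc <- which(vapply(gr$edges, function(e) e$from == v || e$to == v, TRUE))
    if (length(inc) != 2) return(gr)  # self-loop guard
    e1 <- gr$edges[[inc[1]]]; e2 <- gr$edges[[inc[2]]]
    # orient both paths to run through v
    if (e1$to != v) { e1$path <- e1$path[nrow(e1$path):1, , drop = FALSE]
                      e1$radii <- rev(e1$radii); tmp <- e1$from; e1$from <- e1$to; e1$to <- tmp }
    if (e2$from != v) { e2$path <- e2$path[nrow(e2$path):1, , drop = FALSE]
                        e2$radii <- rev(e2$radii); tmp <- e2$from; e2$from <- e2$to; e2$to <- tmp }
    # drop the former junction point itself: a pruned junction's centroid
    # sits off the vessel axis and would put a dogleg into the merged run
    n1 <- nrow(e1$path); n2 <- nrow(e2$path)
    keep1 <- if (n1 > 1) seq_len(n1 - 1) else 1
    keep2 <- if (n2 > 1) 2:n2 else 1
    merged <- list(id = NA_integer_, from = e1$from, to = e2$to,
                   path = smooth_path(rbind(e1$path[keep1, , drop = FALSE],
                                            e2$path[keep2, , drop = FALSE])),
                   radii = c(e1$radii[keep1], e2$radii[keep2]))
    gr$edges <- c(gr$edges[-inc], list(merged))
    for (k in seq_along(gr$edges)) gr$edges[[k]]$id <- k
    gr <- graph_drop_isolated(gr)
  }
}

# Extend terminal centerlines into the vessel end caps: walk from each tip
# along the mean direction of the last polyline points while still inside
# the mask (medial-axis skeletons stop about one radius short of the end).
graph_extend_tips <- function(gr, mask) {
  deg <- graph_degrees(gr)
  sp <- gr$spacing
  dims <- dim(mask$values)
  inside <- function(p) {
    idx <- world_to_voxel(mask, p)
    all(idx >= 1) && all(idx <= dims) && mask$values[idx[1], idx[2], idx[3]]
  }
  for (k in seq_along(gr$edges)) {
    e <- gr$edges[[k]]
    for (endname in c("from", "to")) {
      v <- e[[endname]]
      if (deg[v] != 1) next
      path <- e$path; rr <- e$radii
      if (endname == "from") { path <- path[nrow(path):1, , drop = FALSE]; rr <- rev(rr) }
      np <- nrow(path)
      if (np < 2) next
      tail_pts <- path[max(1, np - 4):np, , drop = FALSE]
      d <- unit3(tail_pts[nrow(tail_pts), ] - tail_pts[1, ])
      p <- path[np, ]
      r_tip <- rr[np]
      travelled <- 0
      while (travelled < 3 * r_tip && inside(p + d * sp / 2)) {
        p <- p + d * sp / 2
        travelled <- travelled + sp / 2
      }
      if (travelled > 0) {
        path <- rbind(path, p); rr <- c(rr, rr[np])
        if (endname == "from") { path <- path[nrow(path):1, , drop = FALSE]; rr <- rev(rr) }
        e$path <- path; e$radii <- rr
        # move the tip node to the extended endpoint
        gr$nodes[v, c("x", "y", "z")] <- as.list(p)
        gr$edges[[k]] <- e
      }
    }
  }
  gr
}

#' Vessel mask to centerline graph in one call
#'
#' Convenience wrapper: optional morphological closing (fills sub-voxel
#' background wedges at bifurcations, which otherwise produce spurious
#' digital handles under 26-connectivity), then [skeletonize()],
#' [estimate_radii()], and [build_graph()].
#'
#' @inheritParams build_graph
#' @param mask vessel [binary_mask()].
#' @param close_gaps apply a 3x3x3 morphological closing first
#'   (default TRUE).
#' @param ... passed to [build_graph()].
#' @return A `vascular_graph`.
#' @export
vascular_graph_from_mask <- function(mask, root_point, close_gaps = TRUE, ...) {
  if (close_gaps) {
    dims <- dim(mask$values)
    mask <- binary_mask(array(box_closing_cpp(mask$values, dims), dims),
                        mask$spacing, mask$origin)
  }
  sk <- skeletonize(mask)
  rr <- estimate_radii(mask, sk)
  build_graph(sk, rr, root_point, mask = mask, ...)
}
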