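#' Convert a centerline graph to a strictly bifurcative cylinder tree
#'
#' Each graph edge becomes a straight cylinder from node to node whose
#' constant radius is the length-weighted mean of the per-point centerline
#' radii. Nodes with more than two outgoing branches are split into nested
#' bifurcations by inserting epsilon-length connector edges (epsilon =
#' spacing / 10), pairing the two largest-radius children first; connector
#' edges are flagged and carry the larger paired radius. Children of every
#' bifurcation are ordered by descending radius.
#'
#' @param graph a `vascular_graph` from [build_graph()].
#' @param epsilon connector edge length (mm); default `spacing / 10`.
#' @return A [vascular_tree()].
#' @export
graph_to_tree <- function(graph, epsilon = NULL) {
  stopifnot(inherits(graph, "vascular_graph"))
  if (is.null(epsilon)) epsilon <- graph$spacing / 10
  nodes <- graph$nodes
  edges <- graph$edges
  if (!length(edges)) stop("graph has no edges")

  ig <- graph_igraph(graph)
  if (igraph::ecount(ig) != igraph::vcount(ig) - igraph::components(ig)$no)
    stop("graph contains cycles; break loops before tree conversion")
  comp <- igraph::components(ig)$membership
  if (any(comp != comp[graph$root]))
    stop("graph is disconnected; keep only the root component first")

  # orient edges away from the root
  incident <- vector("list", nrow(nodes))
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    incident[[e$from]] <- c(incident[[e$from]], k)
    incident[[e$to]] <- c(incident[[e$to]], k)
  }
  wmean_radius <- function(e) {
    p <- e$path
    if (nrow(p) < 2) return(mean(e$radii))
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    rseg <- (e$radii[-1] + e$radii[-length(e$radii)]) / 2
    if (sum(seg) < .Machine$double.eps) return(mean(e$radii))
    sum(rseg * seg) / sum(seg)
  }

  rows <- list()
  nid <- 0L
  emit <- function(parent, from, to, radius, connector = FALSE) {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(id = nid, parent = parent,
                               x0 = from[1], y0 = from[2], z0 = from[3],
                               x1 = to[1], y1 = to[2], z1 = to[3],
                               radius = radius, lobe = "trunk",
                               connector = connector)
    nid
  }
  node_pos <- function(v) as.numeric(nodes[v, c("x", "y", "z")])

  visited_edge <- rep(FALSE, length(edges))
  via <- integer(length(edges))  # node through which each edge is entered

  other_node <- function(k) {
    e <- edges[[k]]
    if (via[k] == e$from) e$to else e$from
  }

  # cylinder for graph edge k, then recurse into the branches at its far node
  descend <- function(parent_edge_id, at_pos, k) {
    exit_node <- other_node(k)
    eid <- emit(parent_edge_id, at_pos, node_pos(exit_node),
                wmean_radius(edges[[k]]))
    kids <- Filter(function(kk) !visited_edge[kk], incident[[exit_node]])
    if (length(kids)) {
      visited_edge[kids] <<- TRUE
      via[kids] <<- exit_node
      attach(eid, node_pos(exit_node), kids)
    }
    eid
  }

  # attach child graph edges under parent_edge_id; multifurcations become
  # nested bifurcations, the two largest-radius children paired deepest
  attach <- function(parent_edge_id, at_pos, child_ks) {
    radii <- vapply(edges[child_ks], wmean_radius, 0)
    ord <- order(radii, -seq_along(radii), decreasing = TRUE)
    child_ks <- child_ks[ord]
    k <- length(child_ks)
    if (k == 1) {
      descend(parent_edge_id, at_pos, child_ks[1])
    } else if (k == 2) {
      for (kk in child_ks) descend(parent_edge_id, at_pos, kk)
    } else {
      rest <- child_ks[seq_len(k - 1)]  # the k-1 largest, paired deeper
      dir <- unit3(rowMeans(vapply(rest, function(kk)
        unit3(node_pos(other_node(kk)) - at_pos), numeric(3))))
      cpos <- at_pos + epsilon * dir
      cid <- emit(parent_edge_id, at_pos, cpos,
                  max(vapply(edges[rest], wmean_radius, 0)),
                  connector = TRUE)
      attach(cid, cpos, rest)
      descend(parent_edge_id, at_pos, child_ks[k])
    }
    invisible(NULL)
  }

  root_edges <- incident[[graph$root]]
  rpos <- node_pos(graph$root)
  visited_edge[root_edges] <- TRUE
  via[root_edges] <- graph$root
  if (length(root_edges) == 1) {
    descend(NA_integer_, rpos, root_edges)
  } else {
    # root node with several branches: epsilon root stem, then bifurcations
    dirs <- vapply(root_edges, function(k)
      unit3(node_pos(other_node(k)) - rpos), numeric(3))
    spos <- rpos + epsilon * unit3(rowMeans(dirs))
    rid <- emit(NA_integer_, rpos, spos,
                max(vapply(edges[root_edges], wmean_radius, 0)),
                connector = TRUE)
    attach(rid, spos, root_edges)
  }

  e <- do.call(rbind, rows)
  tr <- vascular_tree(e, validate = FALSE)
  validate_tree_structure(tr)
  tr
}

# structural validation that tolerates connector-shifted child starts
validate_tree_structure <- function(tree) {
  e <- tree$edges
  root <- which(is.na(e$parent))
  if (length(root) != 1) stop("tree must have exactly one root edge")
  known <- !is.na(e$parent)
  nch <- tabulate(match(e$parent[known], e$id), nbins = nrow(e))
  if (any(!nch %in% c(0L, 2L)))
    stop("tree conversion produced a non-bifurcative node")
  invisible(tree)
}
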