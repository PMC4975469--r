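#' Strictly bifurcative vascular cylinder trees
#'
#' The analysis object of the workflow: a set of straight, constant-radius
#' cylinder edges forming a rooted tree in which every internal node has
#' exactly two child edges. `edges` is a data frame with columns `id`,
#' `parent` (NA for the root), `x0 y0 z0 x1 y1 z1` (mm), `radius` (mm),
#' `lobe` (anatomical lobe label, `"trunk"` when unlabeled) and `connector`
#' (TRUE for the epsilon-length edges inserted when splitting
#' multifurcations). A child edge starts where its parent ends.
#'
#' @param edges edge data frame as described above.
#' @param domain optional ellipsoidal liver domain,
#'   `list(center, semiaxes)` in mm (used by growth transforms and the
#'   voxelizer).
#' @param validate check the tree invariants (default TRUE).
#' @return An object of class `vascular_tree`.
#' @export
vascular_tree <- function(edges, domain = NULL, validate = TRUE) {
  needed <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1", "radius")
  if (!all(needed %in% names(edges)))
    stop("edges must have columns ", paste(needed, collapse = ", "))
  if (is.null(edges$lobe)) edges$lobe <- "trunk"
  if (is.null(edges$connector)) edges$connector <- FALSE
  edges$id <- as.integer(edges$id)
  edges$parent <- as.integer(edges$parent)
  rownames(edges) <- NULL
  tr <- structure(list(edges = edges, domain = domain),
                  class = "vascular_tree")
  if (validate) validate_tree(tr)
  tr
}

validate_tree <- function(tree, tol = 1e-6) {
  e <- tree$edges
  if (nrow(e) == 0) return(invisible(tree))
  if (anyDuplicated(e$id)) stop("duplicate edge ids")
  root <- which(is.na(e$parent))
  if (length(root) != 1) stop("tree must have exactly one root edge")
  if (any(e$radius <= 0)) stop("all radii must be positive")
  known <- !is.na(e$parent)
  if (any(!e$parent[known] %in% e$id)) stop("parent ids must exist")
  nch <- tabulate(match(e$parent[known], e$id), nbins = nrow(e))
  if (any(!nch %in% c(0L, 2L)))
    stop("tree must be strictly bifurcative (0 or 2 children per edge)")
  # acyclicity + attachment: walk each edge to the root
  pos <- match(e$parent, e$id)
  depth <- rep(NA_integer_, nrow(e))
  for (i in seq_len(nrow(e))) {
    j <- i; steps <- 0
    while (!is.na(pos[j])) {
      pj <- pos[j]
      dd <- sqrt((e$x0[j] - e$x1[pj])^2 + (e$y0[j] - e$y1[pj])^2 +
                   (e$z0[j] - e$z1[pj])^2)
      if (dd > tol)
        stop("edge ", e$id[j], " does not start at the end of its parent")
      j <- pj; steps <- steps + 1
      if (steps > nrow(e)) stop("cycle detected in tree")
    }
    depth[i] <- steps
  }
  invisible(tree)
}

#' @export
print.vascular_tree <- function(x, ...) {
  e <- x$edges
  cat(sprintf("<vascular_tree> %d edges (%d tips, %d connectors), total length %.2f mm\n",
              nrow(e), length(tip_ids(x)), sum(e$connector),
              total_edge_length(x)))
  lb <- table(e$lobe)
  cat("  lobes:", paste(sprintf("%s(%d)", names(lb), lb), collapse = " "), "\n")
  invisible(x)
}

#' Root edge id of a vascular tree
#' @param tree a [vascular_tree()].
#' @return Integer edge id of the root cylinder.
#' @export
root_id <- function(tree) tree$edges$id[is.na(tree$edges$parent)]

children_map <- function(tree) {
  e <- tree$edges
  split(e$id[!is.na(e$parent)], factor(e$parent[!is.na(e$parent)], levels = e$id))
}

#' Tip, edge-length and direction helpers
#'
#' @param tree a [vascular_tree()].
#' @return `tip_ids`: ids of terminal edges; `edge_lengths`: named vector of
#'   Euclidean start-end lengths (mm); `edge_directions`: matrix of unit
#'   direction vectors.
#' @export
tip_ids <- function(tree) {
  e <- tree$edges
  setdiff(e$id, e$parent[!is.na(e$parent)])
}

#' @rdname tip_ids
#' @export
edge_lengths <- function(tree) {
  e <- tree$edges
  stats::setNames(sqrt((e$x1 - e$x0)^2 + (e$y1 - e$y0)^2 + (e$z1 - e$z0)^2),
                  e$id)
}

#' @rdname tip_ids
#' @export
edge_directions <- function(tree) {
  e <- tree$edges
  v <- cbind(e$x1 - e$x0, e$y1 - e$y0, e$z1 - e$z0)
  len <- sqrt(rowSums(v^2))
  out <- v / pmax(len, .Machine$double.eps)
  rownames(out) <- e$id
  out
}

descendant_ids <- function(tree, ids) {
  e <- tree$edges
  keep <- e$id %in% ids
  repeat {
    grow <- !keep & e$parent %in% e$id[keep]
    if (!any(grow)) break
    keep <- keep | grow
  }
  e$id[keep]
}

#' Strahler stream orders of a vascular tree
#'
#' Terminal edges have order 1; an edge whose children have orders (a, b)
#' gets max(a, b) when they differ and a + 1 when equal. With
#' multifurcations split largest-pair-first into nested bifurcations, this
#' reproduces the generalized multifurcation Strahler rule, and connector
#' edges automatically carry the order of the bifurcation they host.
#'
#' @param tree a [vascular_tree()].
#' @return Integer vector of orders, named by edge id, in edge-table order.
#' @export
strahler_orders <- function(tree) {
  e <- tree$edges
  n <- nrow(e)
  ord <- stats::setNames(rep(NA_integer_, n), e$id)
  if (n == 0) return(ord)
  ch <- children_map(tree)
  # process edges deepest-first
  pos <- match(e$parent, e$id)
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i; d <- 0
    while (!is.na(pos[j])) { j <- pos[j]; d <- d + 1 }
    depth[i] <- d
  }
  for (i in order(depth, decreasing = TRUE)) {
    kids <- ch[[as.character(e$id[i])]]
    if (is.null(kids) || length(kids) == 0) {
      ord[i] <- 1L
    } else {
      a <- ord[as.character(kids)]
      ord[i] <- if (a[1] == a[2]) a[1] + 1L else max(a)
    }
  }
  ord
}

#' Label anatomical lobes on a vascular tree
#'
#' Each assignment names a subtree root edge; the whole subtree below it
#' (inclusive) carries the lobe label. Unassigned edges keep the label
#' `"trunk"`. Supported labels follow mouse liver anatomy: LLL, LML, RML,
#' RIL, RSL, CIL, CSL, plus "trunk".
#'
#' @param tree a [vascular_tree()].
#' @param assignments named character vector or list: names are edge ids,
#'   values are lobe labels.
#' @return The relabeled tree.
#' @export
label_lobes <- function(tree, assignments) {
  labels_ok <- c("LLL", "LML", "RML", "RIL", "RSL", "CIL", "CSL", "trunk")
  lab <- unlist(assignments)
  if (!all(lab %in% labels_ok))
    stop("unsupported lobe label(s): ",
         paste(setdiff(lab, labels_ok), collapse = ", "))
  ids <- as.integer(names(lab))
  if (any(!ids %in% tree$edges$id)) stop("assignment root edge(s) not in tree")
  e <- tree$edges
  e$lobe <- "trunk"
  assigned <- rep(FALSE, nrow(e))
  for (k in seq_along(ids)) {
    sub <- descendant_ids(tree, ids[k])
    hit <- e$id %in% sub
    if (any(assigned & hit))
      stop("overlapping lobe assignments (edge(s) assigned twice)")
    e$lobe[hit] <- lab[k]
    assigned <- assigned | hit
  }
  tree$edges <- e
  tree
}

#' Read and write vascular trees
#'
#' The JSON dialect is lossless: edges, geometry, radii, lobe labels,
#' connector flags and the domain round-trip exactly. SWC (the standard
#' neuromorphology exchange format, one sample per cylinder endpoint) keeps
#' geometry and radii but has no lobe field, so labels default to `"trunk"`
#' on re-import.
#'
#' @param tree a [vascular_tree()].
#' @param path file path.
#' @return `read_*`: a [vascular_tree()]; `write_*`: `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  payload <- list(format = "livervasc-tree", version = 1L,
                  root = root_id(tree),
                  domain = tree$domain,
                  edges = tree$edges)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  if (!file.exists(path)) stop("cannot read tree: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "livervasc-tree"))
    stop("not a livervasc tree JSON file: ", path)
  e <- as.data.frame(payload$edges)
  dom <- payload$domain
  if (!is.null(dom)) dom <- list(center = as.numeric(dom$center),
                                 semiaxes = as.numeric(dom$semiaxes))
  vascular_tree(e, domain = dom)
}

#' @rdname write_tree_json
#' @export
write_swc <- function(tree, path) {
  e <- tree$edges
  # sample 1 = root start point; sample i+1 = end point of edge ids[i]
  ids <- e$id
  rid <- root_id(tree)
  sample_of_edge <- stats::setNames(seq_along(ids) + 1L, ids)
  root_row <- which(ids == rid)
  lines <- character(nrow(e) + 1L)
  lines[1] <- sprintf("1 2 %.10g %.10g %.10g %.10g -1",
                      e$x0[root_row], e$y0[root_row], e$z0[root_row],
                      e$radius[root_row])
  for (i in seq_len(nrow(e))) {
    par <- if (is.na(e$parent[i])) 1L else sample_of_edge[[as.character(e$parent[i])]]
    lines[i + 1L] <- sprintf("%d 2 %.10g %.10g %.10g %.10g %d",
                             sample_of_edge[[as.character(e$id[i])]],
                             e$x1[i], e$y1[i], e$z1[i], e$radius[i], par)
  }
  writeLines(c("# SWC export: vascular cylinder tree (radii in mm)",
               "# columns: id type x y z radius parent"), path)
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("cannot read SWC file: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop("malformed SWC record at line ", lineno[bad[1]], " of ", path)
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (any(!is.finite(m)))
    stop("non-numeric SWC field at line ",
         lineno[which(rowSums(!is.finite(m)) > 0)[1]], " of ", path)
  sid <- as.integer(m[, 1]); parent <- as.integer(m[, 7])
  known <- parent != -1
  miss <- which(known & !(parent %in% sid))
  if (length(miss))
    stop("SWC parent reference to missing id ", parent[miss[1]],
         " at line ", lineno[miss[1]], " of ", path)
  rootsample <- which(parent == -1)
  if (length(rootsample) != 1) stop("SWC file must have exactly one root sample")
  pos <- match(parent, sid)
  edges <- data.frame(
    id = seq_len(sum(known)),
    parent = NA_integer_,
    x0 = m[pos[known], 3], y0 = m[pos[known], 4], z0 = m[pos[known], 5],
    x1 = m[known, 3], y1 = m[known, 4], z1 = m[known, 5],
    radius = m[known, 6])
  # edge i ends at sample sid[known][i]; its parent edge ends at its start sample
  end_sample <- sid[known]
  edge_of_sample <- stats::setNames(edges$id, end_sample)
  par_sample <- parent[known]
  has_parent_edge <- as.character(par_sample) %in% names(edge_of_sample)
  edges$parent[has_parent_edge] <-
    edge_of_sample[as.character(par_sample[has_parent_edge])]
  vascular_tree(edges)
}
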