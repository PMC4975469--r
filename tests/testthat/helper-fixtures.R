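# Fixture builders and independent brute-force oracles shared by the suite.

# --- manual trees -----------------------------------------------------------

edge_row <- function(id, parent, from, to, radius, lobe = "trunk",
                     connector = FALSE) {
  data.frame(id = id, parent = parent,
             x0 = from[1], y0 = from[2], z0 = from[3],
             x1 = to[1], y1 = to[2], z1 = to[3],
             radius = radius, lobe = lobe, connector = connector)
}

# straight chain along +x (degenerate: single-child edges; validate = FALSE)
chain_tree <- function(lengths, radii = rep(0.3, length(lengths)),
                       dirs = NULL) {
  n <- length(lengths)
  if (is.null(dirs)) dirs <- matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)
  p <- c(0, 0, 0)
  rows <- list()
  for (i in seq_len(n)) {
    q <- p + lengths[i] * dirs[i, ]
    rows[[i]] <- edge_row(i, if (i == 1) NA_integer_ else i - 1L, p, q, radii[i])
    p <- q
  }
  vascular_tree(do.call(rbind, rows), validate = FALSE)
}

# symmetric Y: trunk along +z, daughters at +/- `half_angle` degrees in xz
y_tree <- function(half_angle = 30, trunk_len = 2, daughter_len = 1.5,
                   r_trunk = 0.4) {
  a <- half_angle * pi / 180
  r_d <- r_trunk * (1 / 2)^(1 / 3)
  top <- c(0, 0, trunk_len)
  rows <- rbind(
    edge_row(1, NA_integer_, c(0, 0, 0), top, r_trunk),
    edge_row(2, 1L, top, top + daughter_len * c(sin(a), 0, cos(a)), r_d),
    edge_row(3, 1L, top, top + daughter_len * c(-sin(a), 0, cos(a)), r_d))
  vascular_tree(rows)
}

# perfect binary tree of given depth (root edge at depth 0)
perfect_tree <- function(depth = 3, r_root = 0.4, len = 1) {
  rows <- list(edge_row(1, NA_integer_, c(0, 0, 0), c(0, 0, len), r_root))
  nid <- 1L
  level <- data.frame(id = 1L, x = 0, y = 0, z = len, spread = 4)
  for (d in seq_len(depth)) {
    nxt <- NULL
    r <- r_root * (2^-d)^(1 / 3)
    for (k in seq_len(nrow(level))) {
      for (s in c(-1, 1)) {
        nid <- nid + 1L
        from <- c(level$x[k], level$y[k], level$z[k])
        to <- from + c(s * level$spread[k] / 2, if (d %% 2) 0.3 else -0.3, len)
        rows[[nid]] <- edge_row(nid, level$id[k], from, to, r)
        nxt <- rbind(nxt, data.frame(id = nid, x = to[1], y = to[2], z = to[3],
                                     spread = level$spread[k] / 2))
      }
    }
    level <- nxt
  }
  vascular_tree(do.call(rbind, rows))
}

# small random phantom: fast to generate and to rasterize
small_params <- function(seed, n_tips = 8, min_radius = 0.1) {
  generator_params(
    n_tips = n_tips,
    domain = liver_domain(semiaxes = c(4.2, 3.2, 2.6)),
    root_radius = min_radius * n_tips^(1 / 3) * 1.05,
    min_radius = min_radius,
    seed = seed)
}

pipeline_params <- function(seed) {
  generator_params(n_tips = 32, root_radius = 0.48, min_radius = 0.15,
                   seed = seed)
}

tree_root_point <- function(tree) {
  as.numeric(tree$edges[is.na(tree$edges$parent), c("x0", "y0", "z0")])
}

# --- independent oracles ----------------------------------------------------

oracle_total_edge_length <- function(tree) {
  e <- tree$edges
  s <- 0
  for (i in seq_len(nrow(e)))
    s <- s + sqrt((e$x1[i] - e$x0[i])^2 + (e$y1[i] - e$y0[i])^2 +
                    (e$z1[i] - e$z0[i])^2)
  s
}

oracle_total_vascular_volume <- function(tree) {
  e <- tree$edges
  s <- 0
  for (i in seq_len(nrow(e))) {
    L <- sqrt((e$x1[i] - e$x0[i])^2 + (e$y1[i] - e$y0[i])^2 +
                (e$z1[i] - e$z0[i])^2)
    s <- s + pi * e$radius[i]^2 * L
  }
  s / 1000
}

# enumerate every root-to-tip path explicitly
oracle_maximal_vessel_length <- function(tree) {
  e <- tree$edges
  len <- function(i) sqrt((e$x1[i] - e$x0[i])^2 + (e$y1[i] - e$y0[i])^2 +
                            (e$z1[i] - e$z0[i])^2)
  walk <- function(id, acc) {
    i <- match(id, e$id)
    acc <- acc + len(i)
    kids <- e$id[!is.na(e$parent) & e$parent == id]
    if (!length(kids)) return(acc)
    max(vapply(kids, walk, 0, acc = acc))
  }
  walk(e$id[is.na(e$parent)], 0)
}

oracle_strahler <- function(tree) {
  e <- tree$edges
  rec <- function(id) {
    kids <- e$id[!is.na(e$parent) & e$parent == id]
    if (!length(kids)) return(1L)
    k <- vapply(kids, rec, 0L)
    if (length(k) == 2 && k[1] == k[2]) k[1] + 1L else max(k)
  }
  vapply(e$id, rec, 0L)
}

oracle_branching_angles <- function(tree) {
  e <- tree$edges
  dir <- function(i) {
    v <- c(e$x1[i] - e$x0[i], e$y1[i] - e$y0[i], e$z1[i] - e$z0[i])
    v / sqrt(sum(v^2))
  }
  deg <- function(u, v) acos(min(1, max(-1, sum(u * v)))) * 180 / pi
  out <- NULL
  for (i in seq_len(nrow(e))) {
    if (e$connector[i]) next
    kids <- which(!is.na(e$parent) & e$parent == e$id[i] & !e$connector)
    if (length(kids) != 2) next
    u <- dir(i); a <- dir(kids[1]); b <- dir(kids[2])
    out <- rbind(out,
                 data.frame(type = "deviation", angle = deg(u, a)),
                 data.frame(type = "deviation", angle = deg(u, b)),
                 data.frame(type = "inter_daughter", angle = deg(a, b)))
  }
  out
}

# nearest cylinder centerline segment for one world point, by direct search
oracle_nearest_label <- function(tree, point) {
  e <- tree$edges
  best <- Inf; lab <- NA_character_
  for (i in seq_len(nrow(e))) {
    p0 <- c(e$x0[i], e$y0[i], e$z0[i]); p1 <- c(e$x1[i], e$y1[i], e$z1[i])
    v <- p1 - p0; w <- point - p0
    vv <- sum(v * v)
    t <- if (vv > 0) min(1, max(0, sum(w * v) / vv)) else 0
    d <- sqrt(sum((w - t * v)^2))
    if (d < best - 1e-12 ||
        (d <= best + 1e-12 && !is.na(lab) && e$lobe[i] < lab)) {
      best <- min(best, d)
      lab <- e$lobe[i]
    }
  }
  lab
}

murray_residuals <- function(tree) {
  e <- tree$edges
  out <- numeric(0)
  for (id in unique(e$parent[!is.na(e$parent)])) {
    kids <- which(!is.na(e$parent) & e$parent == id)
    if (length(kids) != 2) next
    rp <- e$radius[match(id, e$id)]
    out <- c(out, abs(rp^3 - sum(e$radius[kids]^3)) / rp^3)
  }
  out
}
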