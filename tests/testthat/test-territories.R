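box_mask <- function(dims = c(20, 20, 20), spacing = 0.1,
                     origin = -spacing * (dims - 1) / 2) {
  binary_mask(array(TRUE, dims), spacing, origin)
}

# two parallel vessels straddling the y = 0 plane, labels LLL / RIL
parallel_tree <- function(offset = 0.5) {
  rows <- rbind(
    edge_row(1, NA_integer_, c(-2, -offset, 0), c(2, -offset, 0), 0.2,
             lobe = "LLL"),
    edge_row(2, NA_integer_, c(-2, offset, 0), c(2, offset, 0), 0.2,
             lobe = "RIL"))
  vascular_tree(rows, validate = FALSE)
}

test_that("two parallel vessels split a box at the midplane", {
  m <- box_mask(c(21, 21, 11))
  tm <- compute_territories(parallel_tree(), m)
  y <- (seq_len(21) - 1) * 0.1 + m$origin[2]
  lab_lll <- match("LLL", tm$levels)
  for (k in c(2, 6, 10)) {
    slab <- tm$labels[, , k]
    expect_true(all(slab[, y < -1e-9] == lab_lll))
    expect_true(all(slab[, y > 1e-9] != lab_lll))
  }
  # symmetry: volumes equal within one voxel volume
  tv <- territory_volumes(tm)
  expect_lt(abs(tv$volume_ml[1] - tv$volume_ml[2]), 0.1^3 / 1000 * 21 * 11 + 1e-12)
})

test_that("a single-label tree claims the whole mask", {
  m <- box_mask(c(10, 10, 10))
  tr <- vascular_tree(edge_row(1, NA_integer_, c(-1, 0, 0), c(1, 0, 0), 0.2,
                               lobe = "RIL"), validate = FALSE)
  tm <- compute_territories(tr, m)
  expect_true(all(tm$labels[m$values] == match("RIL", tm$levels)))
})

test_that("territory assignment agrees with the brute-force nearest-segment oracle", {
  tr <- generate_tree(small_params(71, n_tips = 8))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "RIL"), kids))
  ph <- voxelize(tr, spacing = 0.12, noise_sd = 0)
  tm <- compute_territories(tr, ph$liver)
  idx <- which(tm$labels > 0)
  set.seed(1)
  sample_idx <- sample(idx, 1000)
  ar <- arrayInd(sample_idx, dim(tm$labels))
  world <- voxel_to_world(ph$liver, ar)
  for (k in seq_len(1000)) {
    expect_identical(tm$levels[tm$labels[sample_idx[k]]],
                     oracle_nearest_label(tr, world[k, ]))
  }
})

test_that("territory volumes partition the liver volume exactly", {
  tr <- generate_tree(small_params(72, n_tips = 8))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "RIL"), kids))
  ph <- voxelize(tr, spacing = 0.12, noise_sd = 0)
  tm <- compute_territories(tr, ph$liver)
  tv <- territory_volumes(tm)
  expect_equal(sum(tv$volume_ml), mask_volume_ml(ph$liver), tolerance = 1e-12)
  # unlabeled levels are absent from the table
  expect_false("CSL" %in% tv$lobe)
})

test_that("virtual resection removes labels, restores strict bifurcation", {
  tr <- generate_tree(small_params(73, n_tips = 16))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "RIL"), kids))
  k_removed <- sum(tr$edges$lobe == "LLL")
  rem <- virtual_resection(tr, "LLL")
  expect_false("LLL" %in% rem$edges$lobe)
  # root edge fused with the surviving child: k edges + 1 fusion
  expect_equal(nrow(rem$edges), nrow(tr$edges) - k_removed - 1)
  expect_no_error(livervasc:::validate_tree(rem))
  # empty removal set is the identity
  expect_identical(virtual_resection(tr, character(0))$edges, tr$edges)
  # removing the root's label is refused
  expect_error(virtual_resection(label_lobes(tr, stats::setNames("RIL", root_id(tr))),
                                 "RIL"), "root")
})

test_that("a stump option retains truncated branch stubs", {
  tr <- generate_tree(small_params(74, n_tips = 16))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "RIL"), kids))
  flush <- virtual_resection(tr, "LLL")
  stump <- virtual_resection(tr, "LLL", stump_mm = 0.4)
  expect_gt(nrow(stump$edges), nrow(flush$edges))
  expect_true("LLL" %in% stump$edges$lobe)
  stub_len <- edge_lengths(stump)[stump$edges$lobe == "LLL"]
  expect_true(all(stub_len <= 0.4 + 1e-9))
})

test_that("resecting the larger lobe leaves a remnant like a virtual hepatectomy", {
  # tip split 11/21 puts roughly 2/3 of the parenchyma in one lobe
  tr <- generate_tree(pipeline_params(seed = 75))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "RIL"), kids))
  ph <- voxelize(tr, spacing = 0.15, noise_sd = 0)
  tv <- territory_volumes(compute_territories(tr, ph$liver))
  tv <- tv[tv$lobe != "trunk", ]
  frac <- tv$volume_ml / sum(tv$volume_ml)
  big <- tv$lobe[which.max(frac)]
  rem <- virtual_resection(tr, big)
  # remnant territory fraction is the complement of the removed lobe's
  tv2 <- territory_volumes(compute_territories(rem, ph$liver))
  expect_equal(sum(tv2$volume_ml), mask_volume_ml(ph$liver), tolerance = 1e-12)
  expect_lt(max(frac), 0.85)
  expect_gt(max(frac), 0.5)
})

test_that("lobe extraction equals a brute-force label filter and conserves length", {
  tr <- generate_tree(small_params(76, n_tips = 16))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "RIL"), kids))
  sub <- extract_lobe_subtree(tr, "RIL")
  expect_setequal(sub$edges$id, tr$edges$id[tr$edges$lobe == "RIL"])
  expect_error(extract_lobe_subtree(tr, "CSL"), "not present")
  # extracting the sole label returns the whole tree
  whole <- label_lobes(tr, stats::setNames("RIL", root_id(tr)))
  expect_equal(nrow(extract_lobe_subtree(whole, "RIL")$edges), nrow(tr$edges))
  # conservation of total edge length across labels + trunk
  tot <- sum(vapply(unique(tr$edges$lobe), function(lb) {
    s <- extract_lobe_subtree(tr, lb)
    if (inherits(s, "vascular_tree")) total_edge_length(s)
    else sum(vapply(s, total_edge_length, 0))
  }, 0))
  expect_equal(tot, total_edge_length(tr), tolerance = 1e-9)
})

test_that("resection and extraction commute on disjoint labels", {
  tr <- generate_tree(small_params(77, n_tips = 16))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  gk <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == kids[1]]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "LML", "RIL"),
                                        c(gk[1], gk[2], kids[2])))
  canon <- function(t) {
    e <- t$edges[, c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "lobe")]
    e[do.call(order, e[, 1:7]), ]
  }
  a <- extract_lobe_subtree(virtual_resection(tr, "LLL"), "RIL")
  b <- extract_lobe_subtree(tr, "RIL")
  expect_equal(canon(a), canon(b), ignore_attr = TRUE)
  # remnant of remnant equals removal of the union
  r1 <- virtual_resection(virtual_resection(tr, "LLL"), "LML")
  r2 <- virtual_resection(tr, c("LLL", "LML"))
  expect_equal(canon(r1), canon(r2), ignore_attr = TRUE)
})
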