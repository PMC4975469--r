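test_that("a single-tip request yields one root cylinder and no bifurcation", {
  tr <- generate_tree(small_params(seed = 3, n_tips = 1))
  expect_s3_class(tr, "vascular_tree")
  expect_equal(nrow(tr$edges), 1)
  expect_true(is.na(tr$edges$parent))
  expect_length(tip_ids(tr), 1)
})

test_that("generation is deterministic: same seed gives bitwise-equal trees", {
  p <- small_params(seed = 11)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_tree_json(generate_tree(p), f1)
  write_tree_json(generate_tree(p), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different tree
  f3 <- tempfile(fileext = ".json")
  write_tree_json(generate_tree(small_params(seed = 12)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("Murray's law holds at every bifurcation of a 64-tip tree", {
  p <- generator_params(n_tips = 64, seed = 5)
  tr <- generate_tree(p)
  expect_length(tip_ids(tr), 64)
  res <- murray_residuals(tr)
  expect_gt(length(res), 0)
  expect_lt(max(res), 1e-9)
})

test_that("radii never increase from parent to child along any path", {
  for (seed in 1:4) {
    tr <- generate_tree(small_params(seed, n_tips = 16))
    e <- tr$edges
    kid <- !is.na(e$parent)
    expect_true(all(e$radius[kid] <= e$radius[match(e$parent[kid], e$id)] + 1e-12))
  }
})

test_that("infeasible tip counts fail explicitly instead of truncating", {
  expect_error(
    generate_tree(generator_params(n_tips = 200, root_radius = 0.3,
                                   min_radius = 0.07, seed = 1)),
    "infeasible")
})

test_that("all cylinder endpoints lie inside the liver domain", {
  for (seed in 1:3) {
    tr <- generate_tree(small_params(seed, n_tips = 16))
    pts <- rbind(as.matrix(tr$edges[, c("x0", "y0", "z0")]),
                 as.matrix(tr$edges[, c("x1", "y1", "z1")]))
    expect_true(all(in_domain(pts, tr$domain)))
  }
})

test_that("isotropic growth with lambda 1 is the identity", {
  tr <- generate_tree(small_params(1))
  tr2 <- apply_growth(tr, growth_spec("isotropic", lambda = 1))
  expect_identical(tr2$edges, tr$edges)
})

test_that("isotropic lambda 2 doubles lengths and multiplies volume by 8", {
  tr <- generate_tree(small_params(2))
  tr2 <- apply_growth(tr, growth_spec("isotropic", lambda = 2))
  expect_equal(edge_lengths(tr2), 2 * edge_lengths(tr), tolerance = 1e-12)
  expect_equal(total_vascular_volume(tr2), 8 * total_vascular_volume(tr),
               tolerance = 1e-12)
})

test_that("isotropic scaling commutes with measurement to 1e-9", {
  tr <- generate_tree(small_params(7, n_tips = 16))
  lam <- 1.37
  tr2 <- apply_growth(tr, growth_spec("isotropic", lambda = lam))
  expect_equal(total_edge_length(tr2) / total_edge_length(tr), lam,
               tolerance = 1e-9)
  expect_equal(maximal_vessel_length(tr2) / maximal_vessel_length(tr), lam,
               tolerance = 1e-9)
  expect_equal(total_vascular_volume(tr2) / total_vascular_volume(tr), lam^3,
               tolerance = 1e-9)
  expect_equal(root_radius(tr2) / root_radius(tr), lam, tolerance = 1e-9)
})

test_that("anisotropic scaling changes at least one branching angle by > 1 degree", {
  tr <- generate_tree(small_params(4, n_tips = 16))
  tr2 <- apply_growth(tr, growth_spec("anisotropic", lambda_xyz = c(2, 1, 1)))
  a1 <- oracle_branching_angles(tr)
  a2 <- oracle_branching_angles(tr2)
  expect_equal(nrow(a1), nrow(a2))
  expect_gt(max(abs(a1$angle - a2$angle)), 1)
})

test_that("radius-only dilation leaves geometry untouched", {
  tr <- generate_tree(small_params(5))
  tr2 <- apply_growth(tr, growth_spec("dilation", radius_factor = 1.3))
  expect_identical(tr2$edges[, c("x0", "y0", "z0", "x1", "y1", "z1")],
                   tr$edges[, c("x0", "y0", "z0", "x1", "y1", "z1")])
  expect_equal(tr2$edges$radius, 1.3 * tr$edges$radius, tolerance = 1e-12)
})

test_that("outgrowth adds bifurcations at tips with smaller radii, preserving old topology", {
  tr <- generate_tree(small_params(6, n_tips = 8))
  tr2 <- apply_growth(tr, growth_spec("outgrowth", outgrowth_tips = 3, seed = 2))
  expect_equal(nrow(tr2$edges), nrow(tr$edges) + 6)
  expect_identical(tr2$edges[seq_len(nrow(tr$edges)), ], tr$edges)
  new <- tr2$edges[-seq_len(nrow(tr$edges)), ]
  par_r <- tr$edges$radius[match(new$parent, tr$edges$id)]
  expect_true(all(new$radius < par_r))
  expect_length(tip_ids(tr2), 8 + 3)  # each split tip: -1 tip +2 tips
})

test_that("voxelized cylinder occupancy matches the analytic volume within 10%", {
  sp <- 0.07
  r <- 5 * sp; L <- 100 * sp
  dom <- liver_domain(semiaxes = c(5, 1.5, 1.5))
  tr <- vascular_tree(edge_row(1, NA_integer_, c(-L / 2, 0, 0), c(L / 2, 0, 0), r),
                      domain = dom, validate = FALSE)
  ph <- voxelize(tr, spacing = sp, noise_sd = 0)
  expected <- pi * r^2 * L / sp^3
  expect_lt(abs(sum(ph$vessel_truth$values) / expected - 1), 0.10)
})

test_that("halving the spacing multiplies vessel voxel count by 8 within 10%", {
  dom <- liver_domain(semiaxes = c(4, 1.5, 1.5))
  tr <- vascular_tree(edge_row(1, NA_integer_, c(-3, 0, 0), c(3, 0, 0), 0.3),
                      domain = dom, validate = FALSE)
  n1 <- sum(voxelize(tr, spacing = 0.14, noise_sd = 0)$vessel_truth$values)
  n2 <- sum(voxelize(tr, spacing = 0.07, noise_sd = 0)$vessel_truth$values)
  expect_lt(abs(n2 / n1 / 8 - 1), 0.10)
})

test_that("voxel occupancy error shrinks monotonically as spacing decreases", {
  dom <- liver_domain(semiaxes = c(4, 1.5, 1.5))
  r <- 0.4; L <- 6
  tr <- vascular_tree(edge_row(1, NA_integer_, c(-3, 0, 0), c(3, 0, 0), r),
                      domain = dom, validate = FALSE)
  errs <- vapply(c(0.28, 0.14, 0.07), function(sp) {
    n <- sum(voxelize(tr, spacing = sp, noise_sd = 0)$vessel_truth$values)
    abs(n * sp^3 / (pi * r^2 * L) - 1)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("voxelize rejects trees poking out of the domain and absurd spacings", {
  dom <- liver_domain(semiaxes = c(2, 2, 2))
  out <- vascular_tree(edge_row(1, NA_integer_, c(0, 0, 0), c(5, 0, 0), 0.2),
                       domain = dom, validate = FALSE)
  expect_error(voxelize(out, spacing = 0.1), "outside")
  thin <- vascular_tree(edge_row(1, NA_integer_, c(0, 0, 0), c(1, 0, 0), 0.01),
                        domain = dom, validate = FALSE)
  expect_error(voxelize(thin, spacing = 1.9, margin = 0.2), "coarse")
})

test_that("phantom studies are reproducible and honor the growth truth", {
  p <- small_params(9, n_tips = 8)
  st <- make_phantom_study(p, growth_spec("isotropic", lambda = 1.3),
                           rasterize = FALSE)
  expect_equal(total_edge_length(st$tree_after) /
                 total_edge_length(st$tree_before), 1.3, tolerance = 1e-9)
  # identity growth, rasterized: before and after volumes identical
  st0 <- make_phantom_study(small_params(10, n_tips = 4),
                            growth_spec("isotropic", lambda = 1),
                            spacing = 0.15)
  expect_identical(st0$volume_before$values, st0$volume_after$values)
  # different generator seeds give different trees
  st2 <- make_phantom_study(small_params(11, n_tips = 8),
                            growth_spec("isotropic", lambda = 1.3),
                            rasterize = FALSE)
  expect_false(identical(st$tree_before$edges, st2$tree_before$edges))
})
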