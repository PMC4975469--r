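test_that("visibility thresholds follow theta = f^(1/3) * r_min", {
  expect_equal(visibility_threshold(1, 0.07)$theta, 0.07)
  vt <- visibility_threshold(8, 0.07)
  expect_equal(vt$lambda_expected, 2)
  expect_equal(vt$theta, 0.14)
  expect_equal(visibility_threshold(2.6, 0.07)$theta, 2.6^(1 / 3) * 0.07,
               tolerance = 1e-12)
  expect_error(visibility_threshold(-1, 0.07), "positive")
})

test_that("theta-visible pruning drops sub-threshold edges with their subtrees", {
  ch <- chain_tree(lengths = c(1, 1, 1), radii = c(0.3, 0.2, 0.1))
  kept <- theta_visible_subtree(ch, 0.15)
  expect_equal(nrow(kept$edges), 2)
  expect_setequal(kept$edges$radius, c(0.3, 0.2))
  # theta = 0 keeps everything
  expect_identical(theta_visible_subtree(ch, 0)$edges, ch$edges)
  # root below theta: warning and empty tree
  expect_warning(emp <- theta_visible_subtree(ch, 0.5), "root")
  expect_equal(nrow(emp$edges), 0)
})

test_that("after isotropic growth, theta-visibility recovers exactly the original edge set", {
  tr <- generate_tree(small_params(111, n_tips = 16))
  lam <- 1.3
  r_min <- min(tr$edges$radius)
  tr2 <- apply_growth(tr, growth_spec("isotropic", lambda = lam))
  kept <- theta_visible_subtree(tr2, lam * r_min)
  expect_setequal(kept$edges$id, tr$edges$id)
  # connectivity is preserved: every kept edge's parent is kept or NA
  expect_true(all(is.na(kept$edges$parent) |
                    kept$edges$parent %in% kept$edges$id))
})

test_that("expected isotropic folds are the lambda power laws", {
  f1 <- isotropic_expected_folds(1)
  expect_true(all(f1 == 1))
  f8 <- isotropic_expected_folds(8)
  expect_equal(unname(f8["radius"]), 2)
  expect_equal(unname(f8["total_edge_length"]), 2)
  expect_equal(unname(f8["total_vascular_volume"]), 8)
  expect_equal(unname(f8["edge_length_density"]), 0.25)
  expect_equal(unname(f8["vascular_volume_fraction"]), 1)
  expect_equal(unname(isotropic_expected_folds(2.6)["maximal_vessel_length"]),
               2.6^(1 / 3), tolerance = 1e-12)
})

test_that("branching angles match constructed geometry and an arccos oracle", {
  y <- y_tree(half_angle = 30)
  a <- branching_angles(y)
  dev <- sort(a$angle[a$type == "deviation"])
  expect_equal(dev, c(30, 30), tolerance = 1e-9)
  expect_equal(a$angle[a$type == "inter_daughter"], 60, tolerance = 1e-9)
  # collinear daughter: zero deviation
  rows <- rbind(edge_row(1, NA_integer_, c(0, 0, 0), c(0, 0, 1), 0.3),
                edge_row(2, 1L, c(0, 0, 1), c(0, 0, 2), 0.24),
                edge_row(3, 1L, c(0, 0, 1), c(1, 0, 1.4), 0.2))
  col <- vascular_tree(rows)
  ac <- branching_angles(col)
  expect_equal(min(ac$angle[ac$type == "deviation"]), 0, tolerance = 1e-9)
  # random phantoms against the brute-force oracle
  for (seed in c(112, 113)) {
    tr <- generate_tree(small_params(seed, n_tips = 16))
    got <- branching_angles(tr)
    want <- oracle_branching_angles(tr)
    expect_equal(sort(got$angle[got$type == "deviation"]),
                 sort(want$angle[want$type == "deviation"]), tolerance = 1e-9)
    expect_equal(sort(got$angle[got$type == "inter_daughter"]),
                 sort(want$angle[want$type == "inter_daughter"]),
                 tolerance = 1e-9)
  }
  # a single-cylinder tree has no bifurcation
  expect_warning(none <- branching_angles(chain_tree(1)), "no bifurcation")
  expect_equal(nrow(none), 0)
})

test_that("angle similarity is a bounded, symmetric histogram intersection", {
  a <- c(10, 20, 30, 40, 50)
  expect_equal(angle_similarity(a, a), 1)
  expect_equal(angle_similarity(c(1, 5, 9), c(171, 175, 179)), 0)
  b <- c(15, 25, 35, 45, 60)
  expect_equal(angle_similarity(a, b), angle_similarity(b, a))
  expect_gte(angle_similarity(a, b), 0)
  expect_lte(angle_similarity(a, b), 1)
  expect_error(angle_similarity(numeric(0), a), "nonempty")
  # scale invariance: angles of an isotropically scaled tree are unchanged
  tr <- generate_tree(small_params(114, n_tips = 16))
  tr2 <- apply_growth(tr, growth_spec("isotropic", lambda = 1.7))
  expect_gte(angle_similarity(branching_angles(tr), branching_angles(tr2)),
             0.99)
})

test_that("an isotropic phantom pair is declared compatible with isotropic expansion", {
  tr <- generate_tree(small_params(115, n_tips = 16))
  lam <- 1.3
  tr2 <- apply_growth(tr, growth_spec("isotropic", lambda = lam))
  vb <- ellipsoid_volume_ml(tr$domain)
  cmp <- compare_growth(tr, tr2, vb, vb * lam^3)
  expect_equal(cmp$overall, "compatible")
  expect_true(all(cmp$table$compatible))
  expect_gte(cmp$angle_similarity, 0.99)
  # measured on ground-truth trees, observed/expected ratios are exact
  expect_true(all(abs(cmp$table$ratio - 1) < 1e-6))
})

test_that("a radius-only dilation phantom is flagged on radius and volume", {
  tr <- generate_tree(small_params(116, n_tips = 16))
  tr2 <- apply_growth(tr, growth_spec("dilation", radius_factor = 1.3))
  vb <- ellipsoid_volume_ml(tr$domain)
  cmp <- compare_growth(tr, tr2, vb, vb)
  tab <- cmp$table
  expect_false(tab$compatible[tab$parameter == "radius"])
  expect_false(tab$compatible[tab$parameter == "total_vascular_volume"])
  expect_true(tab$compatible[tab$parameter == "total_edge_length"])
  expect_equal(cmp$overall, "incompatible")
})

test_that("the verdict set grows monotonically with the tolerance", {
  tr <- generate_tree(small_params(117, n_tips = 16))
  tr2 <- apply_growth(tr, growth_spec("dilation", radius_factor = 1.15))
  vb <- ellipsoid_volume_ml(tr$domain)
  tols <- c(0.02, 0.1, 0.2, 0.5)
  n_ok <- vapply(tols, function(tol)
    sum(compare_growth(tr, tr2, vb, vb, tolerance = tol)$table$compatible), 0)
  expect_true(all(diff(n_ok) >= 0))
  expect_equal(n_ok[length(n_ok)], 6)
})

test_that("published fold changes for the regenerated lobe are incompatible with isotropy", {
  observed <- c(radius = 1.4, maximal_vessel_length = 1.3,
                total_edge_length = 2.6, total_vascular_volume = 4.9)
  v <- growth_verdict(observed, volume_fold = 2.6, tolerance = 0.10)
  expect_equal(v$overall, "incompatible")
  tab <- v$table
  # radius and maximal length are close to the lambda expectation ...
  expect_true(tab$compatible[tab$parameter == "radius"])
  expect_true(tab$compatible[tab$parameter == "maximal_vessel_length"])
  # ... but cumulative length and volume far exceed it
  expect_false(tab$compatible[tab$parameter == "total_edge_length"])
  expect_false(tab$compatible[tab$parameter == "total_vascular_volume"])
})
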