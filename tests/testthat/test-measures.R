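test_that("cumulative parameters match hand arithmetic on tiny trees", {
  one <- chain_tree(lengths = 5, radii = 0.3)
  expect_equal(total_edge_length(one), 5)
  expect_equal(maximal_vessel_length(one), 5)
  empty <- vascular_tree(one$edges[0, ], validate = FALSE)
  expect_equal(total_edge_length(empty), 0)
  expect_equal(total_vascular_volume(empty), 0)
  # pi r^2 L for r = L = 1: pi mm^3 = 3.1416e-3 ml
  unit <- chain_tree(lengths = 1, radii = 1)
  expect_equal(total_vascular_volume(unit), pi / 1000, tolerance = 1e-12)
})

test_that("cumulative and circumscribed parameters equal brute-force oracles", {
  for (seed in 81:100) {
    tr <- generate_tree(small_params(seed, n_tips = 1 + seed %% 16))
    expect_equal(total_edge_length(tr), oracle_total_edge_length(tr),
                 tolerance = 1e-12)
    expect_equal(total_vascular_volume(tr), oracle_total_vascular_volume(tr),
                 tolerance = 1e-12)
    expect_equal(maximal_vessel_length(tr), oracle_maximal_vessel_length(tr),
                 tolerance = 1e-12)
  }
})

test_that("maximal vessel length never exceeds total length; equal only for chains", {
  tr <- generate_tree(small_params(101, n_tips = 8))
  expect_lt(maximal_vessel_length(tr), total_edge_length(tr))
  ch <- chain_tree(lengths = c(1, 2, 3))
  expect_equal(maximal_vessel_length(ch), total_edge_length(ch))
  expect_equal(maximal_vessel_length(ch), 6)
})

test_that("path tortuosity is 1 for straight runs and sqrt(2) for a right angle", {
  straight <- chain_tree(lengths = c(1, 1, 1))
  expect_equal(path_tortuosity(straight), 1, tolerance = 1e-12)
  bent <- chain_tree(lengths = c(1, 1),
                     dirs = rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(path_tortuosity(bent), 2 / sqrt(2), tolerance = 1e-12)
  # against an independent computation on a random root-to-tip path
  tr <- generate_tree(small_params(102, n_tips = 8))
  rtl <- livervasc:::root_to_end_lengths(tr)
  tip <- as.integer(names(which.max(rtl[as.character(tip_ids(tr))])))
  e <- tr$edges
  i <- match(tip, e$id); pathlen <- 0
  while (!is.na(i)) {
    pathlen <- pathlen + sqrt((e$x1[i] - e$x0[i])^2 + (e$y1[i] - e$y0[i])^2 +
                                (e$z1[i] - e$z0[i])^2)
    i <- match(e$parent[i], e$id)
  }
  ri <- match(root_id(tr), e$id); ti <- match(tip, e$id)
  straightd <- sqrt((e$x1[ti] - e$x0[ri])^2 + (e$y1[ti] - e$y0[ri])^2 +
                      (e$z1[ti] - e$z0[ri])^2)
  expect_equal(path_tortuosity(tr, root_id(tr), tip), pathlen / straightd,
               tolerance = 1e-12)
  # nodes not on one path are refused
  tips <- tip_ids(tr)
  expect_error(path_tortuosity(tr, tips[1], tips[2]), "path")
})

test_that("root radius reports the root cylinder radius at the measured scale", {
  pv <- chain_tree(lengths = 3, radii = 0.35)
  expect_equal(root_radius(pv), 0.35)
  hv <- chain_tree(lengths = 3, radii = 0.47)
  expect_equal(root_radius(hv), 0.47)
  # a measured root span with radii (0.3, 0.4) equally weighted averages 0.35
  g <- livervasc:::new_vascular_graph(
    data.frame(id = 1:2, x = c(0, 2), y = 0, z = 0, kind = "tip"),
    list(list(id = 1L, from = 1L, to = 2L,
              path = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
              radii = c(0.3, 0.35, 0.4))),
    root = 1L, spacing = 0.07)
  expect_equal(root_radius(graph_to_tree(g)), 0.35, tolerance = 1e-12)
})

test_that("density parameters are ratios with guarded denominators", {
  tr <- chain_tree(lengths = 10, radii = 0.3)
  expect_equal(edge_length_density(tr, 2), 5)
  expect_equal(vascular_volume_fraction(chain_tree(1, radii = 1), 1),
               pi / 1000, tolerance = 1e-12)
  expect_error(edge_length_density(tr, 0), "positive")
  expect_error(vascular_volume_fraction(tr, -1), "positive")
})

test_that("scaling laws hold to 1e-9 on ground-truth trees", {
  tr <- generate_tree(small_params(103, n_tips = 16))
  vol <- ellipsoid_volume_ml(tr$domain)
  for (lam in c(1.3, 2)) {
    tr2 <- apply_growth(tr, growth_spec("isotropic", lambda = lam))
    vol2 <- vol * lam^3
    expect_equal(total_edge_length(tr2) / total_edge_length(tr), lam, tolerance = 1e-9)
    expect_equal(total_vascular_volume(tr2) / total_vascular_volume(tr), lam^3,
                 tolerance = 1e-9)
    expect_equal(edge_length_density(tr2, vol2) / edge_length_density(tr, vol),
                 lam^-2, tolerance = 1e-9)
    expect_equal(vascular_volume_fraction(tr2, vol2) /
                   vascular_volume_fraction(tr, vol), 1, tolerance = 1e-9)
  }
})

test_that("length and volume are additive over lobe subtrees plus trunk", {
  tr <- generate_tree(small_params(104, n_tips = 16))
  kids <- tr$edges$id[!is.na(tr$edges$parent) & tr$edges$parent == root_id(tr)]
  tr <- label_lobes(tr, stats::setNames(c("LLL", "RIL"), kids))
  parts <- lapply(unique(tr$edges$lobe), function(lb) extract_lobe_subtree(tr, lb))
  expect_equal(sum(vapply(parts, total_edge_length, 0)), total_edge_length(tr),
               tolerance = 1e-9)
  expect_equal(sum(vapply(parts, total_vascular_volume, 0)),
               total_vascular_volume(tr), tolerance = 1e-12)
})

test_that("fold increase and recovery reproduce the published arithmetic", {
  expect_equal(fold_increase(929.76, 861.93), 1.0787, tolerance = 1e-4)
  expect_equal(report_fold(fold_increase(929.76, 861.93)), "1.1")
  expect_equal(report_fold(fold_increase(1.22, 0.45)), "2.7")
  expect_equal(fold_increase(3, 3), 1)
  expect_equal(recovery_percent(1.22, 1.35), 90.37, tolerance = 1e-3)
  expect_equal(report_percent(recovery_percent(1.22, 1.35)), "90%")
  expect_equal(report_percent(recovery_percent(326.62, 861.93)), "38%")
  expect_equal(recovery_percent(0, 5), 0)
  expect_error(fold_increase(1, 0), "positive")
  expect_error(recovery_percent(1, -2), "positive")
})

test_that("measurement reports aggregate the individual measures deterministically", {
  tr <- generate_tree(small_params(105, n_tips = 8))
  vol <- ellipsoid_volume_ml(tr$domain)
  rep1 <- measurement_report(tr, vol)
  expect_equal(rep1$total_edge_length, total_edge_length(tr))
  expect_equal(rep1$total_vascular_volume, total_vascular_volume(tr))
  expect_equal(rep1$maximal_vessel_length, maximal_vessel_length(tr))
  expect_equal(rep1$root_radius, root_radius(tr))
  expect_equal(rep1$edge_length_density, edge_length_density(tr, vol))
  rep2 <- measurement_report(tr, vol)
  expect_identical(rep1, rep2)
  # lossless serialization
  back <- unserialize(serialize(rep1, NULL))
  expect_identical(back, rep1)
})

test_that("the synthetic parenchymal table reproduces its generating relation", {
  tb <- simulate_parenchymal_table(n = 24, seed = 4)
  fit <- weight_volume_regression(tb$weight_g, tb$volume_ml)
  expect_lt(abs(fit$slope - 0.907), 0.06)
  expect_gt(fit$r_squared, 0.95)
  dens <- liver_density(tb$weight_g, tb$volume_ml)
  expect_lt(abs(dens$mean - 1.042), 0.05)
  # the import hook fails informatively when the table is missing
  expect_error(read_parenchymal_table(tempfile()), "not found")
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tb, f, row.names = FALSE)
  expect_equal(read_parenchymal_table(f)$weight_g, tb$weight_g)
})
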