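test_that("z-axis filter keeps the boundary and matches a brute recount", {
  pc <- point_cloud(cbind(0, 0, c(-0.1, 0.0, 0.5)))
  expect_equal(nrow(filter_zaxis(pc, 0.0)), 2)
  expect_equal(filter_zaxis(pc, -Inf), pc)          # no-op limit
  big <- rand_cloud(1000, seed = 2)
  kept <- filter_zaxis(big, 0.5)
  expect_equal(nrow(kept), sum(big$z >= 0.5))
  expect_true(all(kept$z >= 0.5))
  # relative order preserved and idempotent
  expect_equal(filter_zaxis(kept, 0.5), kept)
})

test_that("greenness filter applies the excess-green rule per point", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)),
                    rbind(c(0, 1, 0), c(0.5, 0.5, 0.5)),
                    color_dialect = "float01")
  kept <- filter_greenness(pc, 0.2)
  expect_equal(nrow(kept), 1)       # pure green (ExG = 2) stays, gray goes
  expect_equal(kept$g, 1)
  rc <- rand_cloud(400, seed = 5, colors = TRUE)
  kept <- filter_greenness(rc, 0.1)
  manual <- 2 * rc$g - rc$r - rc$b > 0.1
  expect_equal(nrow(kept), sum(manual))
  expect_equal(cloud_xyz(kept), cloud_xyz(rc)[manual, , drop = FALSE])
  expect_equal(filter_greenness(kept, 0.1), kept)   # idempotent
  expect_error(filter_greenness(rand_cloud(10), 0.1), "[Dd]isable")
})

test_that("radius outlier filter counts other points in a closed ball", {
  lone <- point_cloud(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 0.001, 0)))
  kept <- filter_radius_outliers(lone, radius = 0.05, min_neighbors = 1)
  expect_equal(nrow(kept), 2)       # the isolated point is removed
  # boundary: distance exactly r counts as inside; self never counts
  pair <- point_cloud(rbind(c(0, 0, 0), c(0.25, 0, 0)))
  expect_equal(nrow(filter_radius_outliers(pair, 0.25, 1)), 2)
  expect_equal(nrow(filter_radius_outliers(pair, 0.2, 1)), 0)
  rc <- rand_cloud(500, seed = 11, scale = 0.3)
  keep <- oracle_radius_keep(rc, 0.05, 5)
  got <- filter_radius_outliers(rc, 0.05, 5)
  expect_equal(cloud_xyz(got), cloud_xyz(rc)[keep, , drop = FALSE])
})

test_that("statistical outlier filter reproduces the mu + n2*sigma rule", {
  th <- 2 * pi * (0:24) / 25        # ring: every 2-NN spacing identical
  ring <- point_cloud(cbind(cos(th), sin(th), 0))
  expect_equal(nrow(filter_statistical_outliers(ring, k = 2, std_mult = 0)),
               25)                  # zero variance: all points survive
  spiked <- point_cloud(rbind(cloud_xyz(ring), c(50, 50, 50)))
  kept <- filter_statistical_outliers(spiked, k = 2, std_mult = 1)
  expect_equal(nrow(kept), 25)      # far outlier crosses the upper bound
  expect_true(max(kept$x) <= 1)
  rc <- rand_cloud(600, seed = 13)
  keep <- oracle_statistical_keep(rc, k = 10, n2 = 0.5)
  got <- filter_statistical_outliers(rc, k = 10, std_mult = 0.5)
  expect_equal(cloud_xyz(got), cloud_xyz(rc)[keep, , drop = FALSE])
  expect_error(filter_statistical_outliers(rand_cloud(5), k = 10,
                                           std_mult = 1), "more than k")
})

test_that("the pipeline applies enabled filters in order and logs removals", {
  rc <- rand_cloud(100, seed = 1, colors = TRUE)
  none <- preprocess_cloud(rc, filter_params(enabled = character(0)))
  expect_equal(cloud_xyz(none), cloud_xyz(rc))      # empty pipeline
  out <- preprocess_cloud(rc, filter_params(
    z_min = 0.2, greenness = -2, radius = 0.5, min_neighbors = 1,
    k = 5, std_mult = 10))
  log <- filter_log(out)
  expect_equal(log$filter, c("zaxis", "greenness", "radius", "statistical"))
  expect_equal(log$n_in[-1], log$n_out[-4])         # chained stage counts
  expect_equal(log$n_out[4], nrow(out))
})

test_that("preprocessing a synthetic canopy removes ground and outliers", {
  canopy <- synthetic_canopy(rng_seed = 3)
  clean <- preprocess_cloud(canopy, filter_params())
  expect_equal(sum(clean$tag == "ground"), 0)
  expect_equal(sum(clean$tag == "pot"), 0)
  n_out_left <- sum(clean$tag == "outlier")
  expect_lte(n_out_left, 2)                         # >= 18 of 20 removed
  # filters only ever subset: every surviving row exists in the input
  expect_true(all(clean$label %in% canopy$label))
  expect_gt(sum(clean$tag == "leaf"), 0.5 * sum(canopy$tag == "leaf"))
})
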