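test_that("a single plane within r1 collapses to one coarse facet", {
  pc <- plane_cloud(80, seed = 3, extent = 0.01)
  feats <- compute_features(pc, feature_params(K = 20, sigma1 = 0.005))
  cf <- coarse_facets(pc, feats, overseg_params(r1 = 0.1, sigma1 = 0.005,
                                                r2 = 0.2))
  expect_equal(length(unique(cf$assignment)), 1)
  expect_equal(sort(unique(cf$assignment)), 1L)
})

test_that("parallel planes are separated by the plane-distance condition", {
  sigma1 <- 0.002
  set.seed(8)
  bot <- cbind(runif(100, 0, 0.05), runif(100, 0, 0.05), 0)
  top <- cbind(runif(100, 0, 0.05), runif(100, 0, 0.05), 10 * sigma1)
  pc <- point_cloud(rbind(bot, top))
  plane_of <- rep(1:2, each = 100)
  feats <- compute_features(pc, feature_params(K = 20, sigma1 = sigma1))
  # r1 spans both planes, normals agree; only condition (iii) can separate
  cf <- coarse_facets(pc, feats, overseg_params(r1 = 0.2, sigma1 = sigma1,
                                                r2 = 0.2))
  for (f in unique(cf$assignment)) {
    expect_equal(length(unique(plane_of[cf$assignment == f])), 1)
  }
})

test_that("perpendicular planes are separated by the normal-angle condition", {
  set.seed(12)
  # vertical wall x=0 and floor z=0, meeting at the y-axis with a small
  # standoff so interior normals are clean
  floor_ <- cbind(runif(150, 0.02, 0.08), runif(150, 0, 0.08), 0)
  wall <- cbind(0, runif(150, 0, 0.08), runif(150, 0.02, 0.08))
  pc <- point_cloud(rbind(floor_, wall))
  plane_of <- rep(1:2, each = 150)
  sigma1 <- 0.1  # deliberately slack so only the angle test can separate
  feats <- compute_features(pc, feature_params(K = 15, sigma1 = sigma1))
  cf <- coarse_facets(pc, feats, overseg_params(r1 = 0.2, theta = 23,
                                                sigma1 = sigma1, r2 = 0.2))
  for (f in unique(cf$assignment)) {
    expect_equal(length(unique(plane_of[cf$assignment == f])), 1)
  }
})

test_that("local K-means splits symmetric data at the Voronoi boundary", {
  pc <- point_cloud(cbind(c(-2, -1.5, -1, 1, 1.5, 2), 0, 0))
  seeds <- rbind(c(-1.5, 0, 0), c(1.5, 0, 0))
  res <- local_kmeans_refine(pc, rep(1:2, each = 3), seeds,
                             overseg_params(r1 = 1, r2 = 10))
  expect_equal(res$assignment, rep(1:2, each = 3))
  expect_equal(res$seeds, rbind(c(-1.5, 0, 0), c(1.5, 0, 0)))
  expect_lte(res$iterations, 2)  # already at the fixed point
})

test_that("refined facets always partition the cloud", {
  for (seed in 1:3) {
    pc <- rand_cloud(300, seed = seed, scale = 0.1)
    feats <- compute_features(pc, feature_params(K = 10, sigma1 = 0.01))
    fs <- oversegment(pc, feats, overseg_params(r1 = 0.02, sigma1 = 0.01,
                                                r2 = 0.05, rng_seed = seed))
    labs <- facet_labels(fs)
    expect_equal(length(labs), 300)
    expect_true(all(labs >= 1 & labs <= nrow(fs$facets)))
    expect_equal(sum(fs$facets$size), 300)          # sizes sum to N
    expect_true(all(fs$facets$size >= 1))           # no empty facet
    expect_equal(as.integer(table(labs)), fs$facets$size)
  }
})

test_that("with a global search sphere K-means equals plain Voronoi", {
  pc <- rand_cloud(400, seed = 17, scale = 0.5)
  feats <- compute_features(pc, feature_params(K = 12, sigma1 = 0.05))
  fs <- oversegment(pc, feats, overseg_params(r1 = 0.1, sigma1 = 0.05,
                                              r2 = 10, max_kmeans_iters = 50))
  seeds <- as.matrix(fs$facets[, c("seed_x", "seed_y", "seed_z")])
  expect_equal(facet_labels(fs), unname(oracle_voronoi(pc, seeds)))
})

test_that("over-segmentation is deterministic given the RNG seed", {
  pc <- rand_cloud(250, seed = 19, scale = 0.1)
  feats <- compute_features(pc, feature_params(K = 10, sigma1 = 0.01))
  p <- overseg_params(r1 = 0.02, sigma1 = 0.01, r2 = 0.05, rng_seed = 42)
  f1 <- oversegment(pc, feats, p)
  f2 <- oversegment(pc, feats, p)
  expect_identical(facet_labels(f1), facet_labels(f2))
  expect_identical(f1$facets, f2$facets)
})

test_that("an empty cloud yields an empty facet set", {
  pc <- point_cloud(matrix(numeric(), ncol = 3))
  feats <- tibble::tibble(nx = numeric(), ny = numeric(), nz = numeric(),
                          smoothness = numeric())
  fs <- oversegment(pc, feats)
  expect_s3_class(fs, "facet_set")
  expect_equal(nrow(fs$facets), 0)
  expect_equal(nrow(fs$assignment), 0)
})

test_that("seed positions stabilize quickly on smooth fixtures", {
  leaf <- synthetic_leaf(points_per_leaf = 400, curvature = 3, rng_seed = 9)
  feats <- compute_features(leaf, feature_params(K = 20, sigma1 = 0.01))
  fs <- oversegment(leaf, feats,
                    overseg_params(r1 = 0.01, sigma1 = 0.01, r2 = 0.04,
                                   max_kmeans_iters = 10))
  expect_lte(fs$kmeans_iterations, 10)
})

test_that("tidy/glance/facet summaries are coherent", {
  pc <- rand_cloud(150, seed = 23, scale = 0.1)
  feats <- compute_features(pc, feature_params(K = 10, sigma1 = 0.01))
  fs <- oversegment(pc, feats, overseg_params(r1 = 0.03, sigma1 = 0.01,
                                              r2 = 0.06))
  td <- tidy(fs)
  gl <- glance(fs)
  expect_equal(nrow(td), gl$n_facets)
  expect_equal(gl$n_points, 150)
  expect_equal(mean(td$size), gl$mean_size)
})
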