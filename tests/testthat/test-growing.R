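test_that("facet adjacency equals the brute-force min-distance relation", {
  # two interleaved grid strips at spacing h are adjacent at eps = 2h
  h <- 0.01
  a <- as.matrix(expand.grid(x = seq(0, 5) * h, y = seq(0, 3) * h, z = 0))
  b <- a; b[, 1] <- b[, 1] + 6 * h
  far <- a; far[, 1] <- far[, 1] + 1
  pc <- point_cloud(rbind(a, b, far))
  labs <- rep(1:3, times = c(nrow(a), nrow(b), nrow(far)))
  adj <- facet_adjacency(labs, pc, adjacency_eps = 2 * h)
  expect_equal(nrow(adj), 1)
  expect_equal(c(adj$facet_i, adj$facet_j), c(1, 2))
  # random partition vs O(N^2) oracle
  rc <- rand_cloud(300, seed = 31, scale = 0.2)
  set.seed(32)
  rl <- sample(1:8, 300, replace = TRUE)
  eps <- 0.02
  adj <- facet_adjacency(rl, rc, adjacency_eps = eps)
  D <- full_dist(rc)
  expected <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    if (min(D[rl == i, rl == j]) <= eps) {
      expected[[length(expected) + 1]] <- c(i, j)
    }
  }
  expected <- do.call(rbind, expected)
  expect_equal(as.matrix(as.data.frame(adj)), expected,
               ignore_attr = TRUE)
})

test_that("facet-plane distance matches an independent PCA computation", {
  scene <- cross_facet_scene(rbind(c(0, 0), c(1, 0)))
  d <- facet_plane_distance(scene$facets, scene$cloud, 1, 2)
  expect_equal(as.numeric(d), 0)                 # coplanar crosses
  # displace facet 2 along facet 1's normal (z) by 0.01
  cl2 <- scene$cloud
  cl2$z[6:10] <- cl2$z[6:10] + 0.01
  fs2 <- leaffacet:::facet_set(cl2, rep(1:2, each = 5),
                               rbind(c(0, 0, 0), c(1, 0, 0.01)))
  expect_equal(as.numeric(facet_plane_distance(fs2, cl2, 1, 2)), 0.01)
  # random facets: independent prcomp-based recomputation
  rc <- rand_cloud(60, seed = 41)
  set.seed(42)
  rl <- sample(1:3, 60, replace = TRUE)
  fs3 <- leaffacet:::facet_set(rc, rl, matrix(0, 3, 3))
  xyz <- cloud_xyz(rc)
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    pc_i <- prcomp(xyz[rl == i, , drop = FALSE])
    n_i <- pc_i$rotation[, 3]
    cj <- colMeans(xyz[rl == j, , drop = FALSE])
    ci <- colMeans(xyz[rl == i, , drop = FALSE])
    expect_equal(as.numeric(facet_plane_distance(fs3, rc, i, j)),
                 abs(sum(n_i * (cj - ci))), tolerance = 1e-9)
  }
})

test_that("coplanar adjacent facets grow into a single leaf", {
  centers <- as.matrix(expand.grid(x = 0:3, y = 0:1))
  scene <- cross_facet_scene(centers)
  leaves <- grow_leaves(scene$facets, scene$cloud,
                        grow_params(sigma2 = 0.01, adjacency_eps = 0.7,
                                    min_leaf_points = 1))
  expect_equal(nrow(leaves$leaves), 1)
  expect_equal(leaves$leaves$n_facets, nrow(centers))
  expect_true(all(leaf_labels(leaves) == 1))
})

test_that("coplanar but disconnected surfaces stay separate leaves", {
  centers <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  scene <- cross_facet_scene(centers)
  leaves <- grow_leaves(scene$facets, scene$cloud,
                        grow_params(sigma2 = 0.01, adjacency_eps = 0.7,
                                    min_leaf_points = 1))
  expect_equal(nrow(leaves$leaves), 2)
  labs <- leaf_labels(leaves)
  expect_equal(length(unique(labs[1:10])), 1)
  expect_equal(length(unique(labs[11:20])), 1)
  expect_false(labs[1] == labs[11])
})

test_that("breadth-first growing covers a 9-facet structure in 4 waves", {
  # facet 1 at the origin; three neighbors one step away; two chains of
  # farther facets so the BFS frontier advances four times
  centers <- rbind(c(0, 0),                       # start
                   c(1, 0), c(-1, 0), c(0, 1),    # wave 1 (3 facets)
                   c(2, 0), c(0, 2),              # wave 2
                   c(3, 0), c(0, 3),              # wave 3
                   c(4, 0))                       # wave 4
  scene <- cross_facet_scene(centers)
  leaves <- grow_leaves(scene$facets, scene$cloud,
                        grow_params(sigma2 = 0.01, adjacency_eps = 0.7,
                                    min_leaf_points = 1))
  expect_equal(nrow(leaves$leaves), 1)
  expect_equal(leaves$leaves$n_facets, 9)
  rounds <- leaves$facet_map$round
  expect_equal(rounds[1], 0)
  expect_equal(max(rounds), 4)
  expect_equal(as.integer(table(rounds)), c(1L, 3L, 2L, 2L, 1L))
})

test_that("tilted neighbors beyond sigma2 do not merge", {
  # second cross lifted 5 mm: center-to-plane distance exceeds sigma2
  scene <- cross_facet_scene(rbind(c(0, 0), c(1, 0)))
  cl <- scene$cloud
  cl$z[6:10] <- cl$z[6:10] + 0.005
  fs <- leaffacet:::facet_set(cl, rep(1:2, each = 5),
                              rbind(c(0, 0, 0), c(1, 0, 0.005)))
  leaves <- grow_leaves(fs, cl, grow_params(sigma2 = 0.003,
                                            adjacency_eps = 1.1,
                                            min_leaf_points = 1))
  expect_equal(nrow(leaves$leaves), 2)
})

test_that("leaves are unions of whole facets and small ones are reported", {
  canopy <- synthetic_canopy(n_leaves = 3, points_per_leaf = 200,
                             ground = FALSE, pot = FALSE, n_outliers = 2,
                             outlier_clearance = 0.08, rng_seed = 7)
  feats <- compute_features(canopy, feature_params(K = 20))
  fs <- oversegment(canopy, feats)
  leaves <- grow_leaves(fs, canopy, grow_params(min_leaf_points = 50))
  fmap <- leaves$facet_map
  labs <- leaf_labels(leaves)
  flabs <- facet_labels(fs)
  # every point's leaf equals its facet's leaf: no facet is split
  expect_equal(labs, fmap$leaf_id[flabs])
  expect_true(all(table(fmap$facet_id) == 1))     # facet in one leaf only
  # the two isolated outliers grow into tiny structures and are discarded
  expect_gte(nrow(leaves$discarded), 1)
  expect_true(all(leaves$discarded$n_points < 50))
  expect_equal(sum(leaves$leaves$n_points) + sum(labs < 0), length(labs))
})

test_that("on flat surfaces, splitting facets never blocks merging", {
  # a long flat strip: few big facets merge into one leaf; many small
  # facets (finer over-segmentation) must still merge into one leaf
  set.seed(50)
  g <- as.matrix(expand.grid(x = seq(0, 0.3, by = 0.004),
                             y = seq(0, 0.05, by = 0.004)))
  g <- g + runif(length(g), -0.001, 0.001)
  strip <- point_cloud(cbind(g, 0))
  feats <- compute_features(strip, feature_params(K = 20, sigma1 = 0.01))
  for (r1 in c(0.08, 0.02)) {
    fs <- oversegment(strip, feats,
                      overseg_params(r1 = r1, sigma1 = 0.01, r2 = 0.1))
    leaves <- grow_leaves(fs, strip, grow_params(sigma2 = 0.003,
                                                 adjacency_eps = 0.01,
                                                 min_leaf_points = 10))
    expect_equal(nrow(leaves$leaves), 1)
  }
})
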