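test_that("point-to-plane distance follows the projection formula", {
  expect_equal(point_plane_distance(c(0, 0, 1), c(0, 0, 0), c(1, 2, 3)), 3)
  expect_equal(point_plane_distance(c(1, 1, 1), c(2, 2, 2), c(2, 2, 2)), 0)
  # scale invariance in the normal
  expect_equal(point_plane_distance(c(0, 0, 2), c(0, 0, 0), c(0, 0, 1)), 1)
  set.seed(4)
  for (i in 1:20) {
    n <- rnorm(3); xi <- rnorm(3); xj <- rnorm(3); s <- runif(1, 0.1, 10)
    expect_equal(point_plane_distance(s * n, xi, xj),
                 point_plane_distance(n, xi, xj))
  }
  expect_error(point_plane_distance(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "[Zz]ero normal")
})

test_that("neighborhood covariance equals the brute-force outer-product sum", {
  X <- t(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)))
  expect_equal(neighborhood_covariance(X), diag(c(0.5, 0.5, 0)))
  same <- matrix(0, 3, 6)
  expect_equal(neighborhood_covariance(same), matrix(0, 3, 3))
  set.seed(9)
  P <- matrix(rnorm(150), ncol = 3)
  Xc <- t(scale(P, scale = FALSE))
  brute <- Reduce(`+`, lapply(seq_len(50), function(i) {
    tcrossprod(Xc[, i])
  })) / 50
  expect_lt(max(abs(neighborhood_covariance(Xc) - brute)), 1e-12)
  expect_error(neighborhood_covariance(matrix(0, 3, 2)), "K >= 3")
})

test_that("iterative PCA on an exact plane keeps all neighbors", {
  pc <- plane_cloud(60, seed = 2)
  res <- ipca_point(pc, 5, feature_params(K = 20, sigma1 = 0.01))
  expect_equal(abs(res$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_gte(res$normal[3], 0)                    # canonical sign
  expect_equal(length(res$inliers), 20)           # nothing removed
  expect_lte(res$iterations, 2)
  expect_false(res$degenerate)
  expect_gt(res$smoothness, 1e6)                  # floored lambda3
})

test_that("a neighbor far off-plane is removed and the plane recovered", {
  sigma1 <- 0.01
  set.seed(6)
  disc <- cbind(runif(30, -0.1, 0.1), runif(30, -0.1, 0.1), 0)
  spike <- c(0, 0.001, 10 * sigma1)   # hovers over the disc
  far <- cbind(runif(10, 5, 6), runif(10, 5, 6), 0)
  pc <- point_cloud(rbind(c(0, 0, 0), disc, spike, far))
  res <- ipca_point(pc, 1, feature_params(K = 32, sigma1 = sigma1))
  expect_false(32 %in% res$inliers)   # the spike (row 32) is rejected
  expect_setequal(res$inliers, 1:31)
  expect_lt(sum(abs(abs(res$normal) - c(0, 0, 1))), 1e-6)
})

test_that("the full feature table is deterministic and self-consistent", {
  pc <- rand_cloud(120, seed = 21, scale = 0.2)
  params <- feature_params(K = 12, sigma1 = 0.02)
  f1 <- compute_features(pc, params)
  f2 <- compute_features(pc, params)
  expect_identical(f1$nx, f2$nx)
  expect_identical(f1$inliers, f2$inliers)
  knn <- attr(f1, "knn")
  for (i in seq_len(nrow(pc))) {
    expect_true(i %in% f1$inliers[[i]])            # anchor never removed
    expect_true(all(f1$inliers[[i]] %in% knn[i, ]))# inliers within K-NN
  }
  expect_true(all(sqrt(f1$nx^2 + f1$ny^2 + f1$nz^2) - 1 < 1e-9))
  expect_true(all(f1$nz >= 0))                     # canonical orientation
})

test_that("two parallel planes far apart never share inlier sets", {
  sigma1 <- 0.005
  set.seed(30)
  top <- cbind(runif(80), runif(80), 10 * sigma1)
  bot <- cbind(runif(80), runif(80), 0)
  pc <- point_cloud(rbind(bot, top))
  plane_of <- rep(c(1, 2), each = 80)
  feats <- compute_features(pc, feature_params(K = 30, sigma1 = sigma1))
  for (i in seq_len(160)) {
    expect_true(all(plane_of[feats$inliers[[i]]] == plane_of[i]))
  }
})

test_that("normals of a sampled curved surface track the analytic normals", {
  leaf <- synthetic_leaf(points_per_leaf = 450, curvature = 6, rng_seed = 4)
  feats <- compute_features(leaf, feature_params(K = 30, sigma1 = 0.01))
  est <- cbind(feats$nx, feats$ny, feats$nz)
  truth <- cbind(leaf$nx, leaf$ny, leaf$nz)
  ang <- acos(pmin(1, abs(rowSums(est * truth)))) * 180 / pi
  # interior points: away from the rim where neighborhoods are one-sided
  rim <- sqrt(leaf$x^2 + leaf$y^2) > 0.8 * max(sqrt(leaf$x^2 + leaf$y^2))
  expect_gt(mean(ang[!rim] < 5), 0.95)
})

test_that("planar patches score smoother than spherical ones", {
  set.seed(40)
  n <- 300
  flat <- point_cloud(cbind(runif(n, -1, 1), runif(n, -1, 1),
                            rnorm(n, 0, 0.005)))
  th <- runif(n, 0, 2 * pi); ph <- acos(runif(n, -1, 1))
  ball <- point_cloud(cbind(sin(ph) * cos(th), sin(ph) * sin(th),
                            cos(ph)) + rnorm(3 * n, 0, 0.005))
  fp <- feature_params(K = 25, sigma1 = 1)
  s_flat <- compute_features(flat, fp)$smoothness
  s_ball <- compute_features(ball, fp)$smoothness
  expect_gt(median(s_flat), median(s_ball))
})

test_that("the inlier set shrinks monotonically across iterations", {
  # indirectly: the final inlier count never exceeds K, and reapplying the
  # removal rule to the final state removes nothing (fixed point)
  pc <- rand_cloud(200, seed = 55, scale = 0.15)
  params <- feature_params(K = 15, sigma1 = 0.01)
  feats <- compute_features(pc, params)
  xyz <- cloud_xyz(pc)
  for (i in sample(200, 25)) {
    inl <- feats$inliers[[i]]
    expect_lte(length(inl), params$K)
    if (feats$degenerate[i]) next
    n <- c(feats$nx[i], feats$ny[i], feats$nz[i])
    d <- abs((xyz[inl, , drop = FALSE] %*% n) - sum(xyz[i, ] * n))
    expect_true(all(d <= params$sigma1 + 1e-12 | inl == i))
  }
})
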