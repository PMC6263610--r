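# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use naive full-matrix / loop formulations (stats::dist,
# prcomp, double loops) so they share no code path with the package's
# chunked, vectorized implementations.

rand_cloud <- function(n, seed = 1, colors = FALSE, scale = 1) {
  set.seed(seed)
  pts <- matrix(runif(3 * n), ncol = 3) * scale
  if (colors) point_cloud(pts, matrix(runif(3 * n), ncol = 3)) else
    point_cloud(pts)
}

plane_cloud <- function(n, seed = 1, extent = 1, noise = 0) {
  set.seed(seed)
  point_cloud(cbind(runif(n, -extent, extent), runif(n, -extent, extent),
                    rnorm(n, 0, noise)))
}

full_dist <- function(cloud) {
  as.matrix(stats::dist(cloud_xyz(cloud)))
}

# O(N^2) radius outlier oracle: keep iff >= n1 OTHER points in closed ball.
oracle_radius_keep <- function(cloud, r, n1) {
  D <- full_dist(cloud)
  diag(D) <- Inf
  rowSums(D <= r) >= n1
}

# O(N^2) statistical outlier oracle: mean k-NN distance vs mu + n2 * sigma.
oracle_statistical_keep <- function(cloud, k, n2) {
  D <- full_dist(cloud)
  diag(D) <- Inf
  d <- apply(D, 1, function(row) mean(sort(row)[seq_len(k)]))
  d <= mean(d) + n2 * sd(d)
}

# Independent iterative-PCA oracle for one point, written as a plain loop
# over setdiff/prcomp (SVD-based eigenvectors, unlike eigen()).
oracle_ipca <- function(cloud, index, K, sigma1, max_iter = 50) {
  xyz <- cloud_xyz(cloud)
  D <- full_dist(cloud)
  nb <- order(D[index, ])  # self first (distance 0)
  inl <- sort(nb[seq_len(K)])
  xi <- xyz[index, ]
  normal <- NULL
  for (it in seq_len(max_iter)) {
    P <- xyz[inl, , drop = FALSE]
    pc <- prcomp(P, center = TRUE, scale. = FALSE)
    normal <- pc$rotation[, 3]
    drop <- inl[abs(as.vector((P - matrix(xi, nrow(P), 3, byrow = TRUE)) %*%
                                normal)) > sigma1]
    drop <- setdiff(drop, index)
    if (length(drop) == 0) break
    nxt <- setdiff(inl, drop)
    if (length(nxt) < 3) { inl <- nxt; break }
    inl <- nxt
  }
  list(inliers = inl, normal = normal)
}

# Brute-force nearest-seed (Voronoi) assignment.
oracle_voronoi <- function(cloud, seeds) {
  xyz <- cloud_xyz(cloud)
  apply(xyz, 1, function(p) {
    which.min(colSums((t(seeds) - p)^2))
  })
}

# Hand-built facet_set: a cloud of small coplanar 5-point crosses at given
# 2D centers (z = 0), one facet per cross.
cross_facet_scene <- function(centers, arm = 0.2) {
  offs <- rbind(c(0, 0), c(arm, 0), c(-arm, 0), c(0, arm), c(0, -arm))
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(sweep(offs, 2, centers[i, ], "+"), 0)
  }))
  cloud <- point_cloud(pts)
  assignment <- rep(seq_len(nrow(centers)), each = nrow(offs))
  seeds <- cbind(centers, 0)
  facets <- leaffacet:::facet_set(cloud, assignment, seeds)
  list(cloud = cloud, facets = facets)
}
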