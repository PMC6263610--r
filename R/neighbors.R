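# Internal neighbor-search helpers. All searches are exact and vectorized,
# processing query points in chunks so the full N x N distance matrix is
# never materialized at once. Cloud sizes this package targets (1e4--1e5
# points, tests at <= 1e4) stay well within memory at chunk size 512.

CHUNK <- 512L

# Squared Euclidean cross-distances between rows of A (m x 3) and B (n x 3).
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k nearest neighbors of every point, self included as the
# first neighbor (distance 0). Returns an N x k integer matrix ordered by
# increasing distance; ties broken by point index (ascending).
knn_indices <- function(xyz, k) {
  n <- nrow(xyz)
  if (k > n) abort(paste0("Requested k = ", k, " neighbors from ", n, " points."))
  out <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1L, n, by = CHUNK)) {
    idx <- start:min(start + CHUNK - 1L, n)
    d2 <- cross_dist2(xyz[idx, , drop = FALSE], xyz)
    for (ii in seq_along(idx)) {
      ord <- order(d2[ii, ], seq_len(n))
      out[idx[ii], ] <- ord[seq_len(k)]
    }
  }
  out
}

# Mean distance from each point to its k nearest neighbors (self excluded).
knn_mean_dist <- function(xyz, k) {
  n <- nrow(xyz)
  if (n <= k) abort(paste0("Need more than k = ", k, " points, got ", n, "."))
  out <- numeric(n)
  for (start in seq(1L, n, by = CHUNK)) {
    idx <- start:min(start + CHUNK - 1L, n)
    d2 <- cross_dist2(xyz[idx, , drop = FALSE], xyz)
    for (ii in seq_along(idx)) {
      d <- sqrt(d2[ii, ])
      d[idx[ii]] <- Inf  # drop self
      out[idx[ii]] <- mean(sort(d, partial = k)[seq_len(k)])
    }
  }
  out
}

# Distance from each point to its single nearest neighbor (self excluded).
nn_spacing <- function(xyz) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (start in seq(1L, n, by = CHUNK)) {
    idx <- start:min(start + CHUNK - 1L, n)
    d2 <- cross_dist2(xyz[idx, , drop = FALSE], xyz)
    for (ii in seq_along(idx)) {
      d2[ii, idx[ii]] <- Inf
      out[idx[ii]] <- sqrt(min(d2[ii, ]))
    }
  }
  out
}

# Number of OTHER points within the closed ball of radius r of each point.
radius_counts <- function(xyz, r) {
  n <- nrow(xyz)
  r2 <- r^2 * (1 + 1e-12)  # closed ball, guard float noise at the boundary
  out <- integer(n)
  for (start in seq(1L, n, by = CHUNK)) {
    idx <- start:min(start + CHUNK - 1L, n)
    d2 <- cross_dist2(xyz[idx, , drop = FALSE], xyz)
    within <- d2 <= r2
    cnt <- rowSums(within) - 1L  # exclude self
    out[idx] <- cnt
  }
  out
}

# All unordered point pairs (i < j) within distance eps of each other,
# returned as a two-column integer matrix.
radius_pairs <- function(xyz, eps) {
  n <- nrow(xyz)
  e2 <- eps^2 * (1 + 1e-12)
  is <- list()
  js <- list()
  part <- 1L
  for (start in seq(1L, n, by = CHUNK)) {
    idx <- start:min(start + CHUNK - 1L, n)
    d2 <- cross_dist2(xyz[idx, , drop = FALSE], xyz)
    hit <- which(d2 <= e2, arr.ind = TRUE)
    gi <- idx[hit[, 1]]
    gj <- hit[, 2]
    keep <- gi < gj
    is[[part]] <- gi[keep]
    js[[part]] <- gj[keep]
    part <- part + 1L
  }
  cbind(i = unlist(is), j = unlist(js))
}
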