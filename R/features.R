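#' Point-to-plane distance
#'
#' Distance from a point `xj` to the plane through `xi` with normal
#' `normal`: \eqn{d = |n^T (x_j - x_i)| / \lVert n \rVert}. Invariant to
#' the scale (and sign) of the normal.
#'
#' @param normal 3-vector, need not be unit length (must be nonzero).
#' @param xi 3-vector, a point on the plane (the plane anchor).
#' @param xj 3-vector, the query point.
#' @return Nonnegative distance in meters; zero iff `xj` lies on the plane.
#' @examples
#' point_plane_distance(c(0, 0, 1), c(0, 0, 0), c(1, 2, 3)) # 3
#' @export
point_plane_distance <- function(normal, xi, xj) {
  nn <- sqrt(sum(normal^2))
  if (nn == 0) abort("Zero normal vector: plane is undefined.")
  abs(sum(normal * (xj - xi))) / nn
}

#' Covariance matrix of a centered neighborhood
#'
#' For a centered 3 x K coordinate matrix `X` (column means already
#' subtracted), returns \eqn{C = X X^T / K}: symmetric, positive
#' semidefinite, the population covariance of the K neighbor positions.
#'
#' @param X 3 x K numeric matrix of centered neighbor coordinates.
#' @return A 3 x 3 covariance matrix.
#' @export
neighborhood_covariance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) != 3) abort("`X` must be a 3 x K matrix (one column per point).")
  K <- ncol(X)
  if (K < 3) abort("Need K >= 3 neighbors for a covariance plane fit.")
  tcrossprod(X) / K
}

#' Feature-estimation parameters
#'
#' @param K neighborhood size for the iterative PCA plane fit (the
#'   initial K-nearest neighbors, the query point included). Default 20,
#'   the small-leaf regime; use 40 for broad-leaf plants.
#' @param sigma1 inlier distance threshold in meters: neighbors farther
#'   than this from the current fitted plane are removed. Default 0.025 m.
#' @param max_iterations safety cap on the iteration count. Convergence is
#'   guaranteed (the inlier set only shrinks), so the cap only guards
#'   pathological floating-point behavior.
#' @param lambda_floor relative numerical floor for the smallest eigenvalue
#'   when forming the smoothness ratio; see Details.
#'
#' @details The smoothness of a point is \eqn{s = \lambda_2 / \lambda_3},
#' the ratio of the middle to the smallest eigenvalue of the neighborhood
#' covariance. On a noiseless plane \eqn{\lambda_3 = 0}, so the ratio is
#' computed as \eqn{\lambda_2 / \max(\lambda_3, \mathrm{floor} \cdot
#' \lambda_1, \epsilon)}; a floored point is reported as maximally smooth.
#'
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(K = 20, sigma1 = 0.025, max_iterations = 50,
                           lambda_floor = 1e-9) {
  stopifnot(K >= 3, sigma1 > 0, max_iterations >= 1, lambda_floor >= 0)
  structure(list(K = as.integer(K), sigma1 = sigma1,
                 max_iterations = as.integer(max_iterations),
                 lambda_floor = lambda_floor),
            class = "feature_params")
}

# Canonical sign for a PCA normal: z >= 0; if z == 0 then y >= 0; if both
# zero then x >= 0. Makes eigenvector sign deterministic across platforms.
canonicalize_normal <- function(n) {
  s <- sign(n[3])
  if (s == 0) s <- sign(n[2])
  if (s == 0) s <- sign(n[1])
  if (s == 0) s <- 1
  n * s
}

smoothness_ratio <- function(lambda, floor_rel) {
  den <- max(lambda[3], floor_rel * lambda[1], .Machine$double.eps)
  lambda[2] / den
}

# One IPCA run for the point at `index`, given its initial K-NN row.
ipca_one <- function(xyz, index, nb0, sigma1, max_iterations, lambda_floor) {
  inliers <- nb0
  xi <- xyz[index, ]
  normal <- c(0, 0, 1)
  smooth <- NA_real_
  degenerate <- FALSE
  iters <- 0L
  repeat {
    iters <- iters + 1L
    P <- xyz[inliers, , drop = FALSE]
    Xc <- t(P) - colMeans(P)
    C <- tcrossprod(Xc) / ncol(Xc)
    ev <- eigen(C, symmetric = TRUE)
    normal <- ev$vectors[, 3]
    smooth <- smoothness_ratio(ev$values, lambda_floor)
    # remove neighbors far from the just-updated plane; the query point
    # anchors the plane and is never removed
    d <- abs((t(P) - xi) |> crossprod(normal))
    keep <- as.vector(d) <= sigma1 | inliers == index
    new_inliers <- inliers[keep]
    if (length(new_inliers) < 3) {
      degenerate <- TRUE
      inliers <- new_inliers
      break
    }
    if (length(new_inliers) == length(inliers) || iters >= max_iterations) {
      inliers <- new_inliers
      break
    }
    inliers <- new_inliers
  }
  list(normal = canonicalize_normal(normal), smoothness = smooth,
       inliers = inliers, iterations = iters, degenerate = degenerate)
}

#' Iterative-PCA features of a single point
#'
#' Runs the iterative PCA plane fit for one point: initialize with the K
#' nearest neighbors (the point itself included); repeatedly fit a plane by
#' eigendecomposition of the centered neighborhood covariance, set the
#' normal to the smallest-eigenvalue eigenvector and the smoothness to
#' \eqn{\lambda_2/\lambda_3}, then drop neighbors farther than `sigma1`
#' from the just-fitted plane; stop when the inlier set stops changing.
#' The K-nearest neighborhood is computed once; iterations only remove
#' points, so the inlier set shrinks monotonically and termination is
#' guaranteed. The query point is never removed (it anchors the plane).
#'
#' @param cloud a point cloud tibble with at least `K + 1` points.
#' @param index 1-based row index of the point.
#' @param params a [feature_params()] object.
#' @return A list: unit `normal` (sign-canonicalized so the z-component is
#'   nonnegative), `smoothness`, integer `inliers` (surviving neighbor row
#'   indices, always containing `index`), `iterations`, and `degenerate`
#'   (`TRUE` when the inlier set fell below 3 and the last valid fit was
#'   kept).
#' @export
ipca_point <- function(cloud, index, params = feature_params()) {
  check_cloud(cloud)
  stopifnot(inherits(params, "feature_params"))
  n <- nrow(cloud)
  if (index < 1 || index > n) abort("`index` out of range.")
  if (n < params$K + 1) {
    abort(paste0("Cloud has ", n, " points; need at least K + 1 = ",
                 params$K + 1, "."))
  }
  xyz <- cloud_xyz(cloud)
  d2 <- cross_dist2(xyz[index, , drop = FALSE], xyz)[1, ]
  nb0 <- order(d2, seq_len(n))[seq_len(params$K)]
  ipca_one(xyz, index, nb0, params$sigma1, params$max_iterations,
           params$lambda_floor)
}

#' Iterative-PCA features of every point
#'
#' Applies [ipca_point()] independently to each point of the cloud. The
#' procedure is deterministic: no randomness is involved.
#'
#' @inheritParams ipca_point
#' @return A tibble aligned with the cloud rows: `id`, unit normal
#'   components `nx`, `ny`, `nz`, `smoothness`, `n_inliers`, `iterations`,
#'   `degenerate`, and a list-column `inliers` of surviving neighbor row
#'   indices. The initial K-NN index matrix and the parameters are attached
#'   as attributes `"knn"` and `"params"` for downstream stages.
#' @examples
#' plane <- point_cloud(cbind(runif(40), runif(40), 0))
#' feats <- compute_features(plane, feature_params(K = 10))
#' head(feats)
#' @export
compute_features <- function(cloud, params = feature_params()) {
  check_cloud(cloud)
  stopifnot(inherits(params, "feature_params"))
  n <- nrow(cloud)
  if (n < params$K + 1) {
    abort(paste0("Cloud has ", n, " points; need at least K + 1 = ",
                 params$K + 1, "."))
  }
  xyz <- cloud_xyz(cloud)
  knn <- knn_indices(xyz, params$K)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- ipca_one(xyz, i, knn[i, ], params$sigma1,
                         params$max_iterations, params$lambda_floor)
  }
  normals <- t(vapply(res, `[[`, numeric(3), "normal"))
  out <- tibble(
    id = seq_len(n),
    nx = normals[, 1], ny = normals[, 2], nz = normals[, 3],
    smoothness = vapply(res, `[[`, numeric(1), "smoothness"),
    n_inliers = lengths(lapply(res, `[[`, "inliers")),
    iterations = vapply(res, `[[`, integer(1), "iterations"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    inliers = lapply(res, `[[`, "inliers")
  )
  attr(out, "knn") <- knn
  attr(out, "params") <- params
  out
}

#' Write a feature table as TSV
#'
#' Serializes the scalar columns of a [compute_features()] result
#' (the inlier list-column is dropped).
#'
#' @param features a feature tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  flat <- features[, c("id", "nx", "ny", "nz", "smoothness",
                       "n_inliers", "iterations")]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
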