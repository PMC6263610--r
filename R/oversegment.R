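#' Over-segmentation parameters
#'
#' @param r1 coarse-growth radius in meters: a point can only join a coarse
#'   facet if it lies within `r1` of the facet's seed. Default 0.03 m.
#' @param theta normal-angle threshold in degrees for the coplanarity test
#'   between a candidate's normal and the seed's normal. Default 23.
#' @param sigma1 point-to-seed-plane distance threshold in meters (shared
#'   with the feature stage). Default 0.025 m.
#' @param r2 local K-means search-sphere radius in meters; must be at least
#'   `r1`. Default 0.1 m.
#' @param max_kmeans_iters iteration cap for the local K-means refinement.
#'   Default 10 (boundaries typically stabilize in 3--5 iterations).
#' @param stability_tol seed positions count as stable when the largest
#'   seed displacement between iterations falls below this (meters).
#' @param rng_seed integer seed for the random visiting order used in seed
#'   selection; fixing it makes the whole stage deterministic.
#' @return A list of class `overseg_params`.
#' @export
overseg_params <- function(r1 = 0.03, theta = 23, sigma1 = 0.025, r2 = 0.1,
                           max_kmeans_iters = 10, stability_tol = 1e-7,
                           rng_seed = 0) {
  stopifnot(r1 > 0, theta > 0, theta < 90, sigma1 > 0, r2 >= r1,
            max_kmeans_iters >= 1, stability_tol > 0)
  structure(list(r1 = r1, theta = theta, sigma1 = sigma1, r2 = r2,
                 max_kmeans_iters = as.integer(max_kmeans_iters),
                 stability_tol = stability_tol,
                 rng_seed = as.integer(rng_seed)),
            class = "overseg_params")
}

#' Coarse facet generation
#'
#' Visits the points in a random order (fixed by `rng_seed`). For each
#' still-unused point, the unused point with the greatest smoothness among
#' its initial K-nearest neighbors is promoted to seed, and the seed's facet
#' grows over all unused points `xk` satisfying simultaneously: (i)
#' `|xk - xseed| <= r1`, (ii) the acute angle between the normals of `xk`
#' and the seed is at most `theta`, and (iii) the distance from `xk` to the
#' seed's fitted plane is at most `sigma1`. Growth is anchored at the seed
#' (it does not chain through accepted members). Points left unused after
#' the pass become singleton facets of themselves, so every point ends in
#' exactly one coarse facet.
#'
#' The angle test uses the acute angle `acos(|nk . nseed|)`: PCA normals
#' are sign-ambiguous, and without the absolute value an exactly coplanar
#' neighbor could fail the test at 180 degrees.
#'
#' @param cloud a point cloud tibble.
#' @param features the matching [compute_features()] table.
#' @param params an [overseg_params()] object.
#' @return A list: `assignment` (integer facet id per point, 1-based) and
#'   `seeds` (F x 3 matrix of seed coordinates, row f = facet f).
#' @export
coarse_facets <- function(cloud, features, params = overseg_params()) {
  check_cloud(cloud)
  stopifnot(inherits(params, "overseg_params"))
  n <- nrow(cloud)
  if (n == 0) {
    return(list(assignment = integer(),
                seeds = matrix(numeric(), ncol = 3)))
  }
  if (nrow(features) != n) {
    abort("`features` is not aligned with `cloud` (row counts differ).")
  }
  xyz <- cloud_xyz(cloud)
  normals <- cbind(features$nx, features$ny, features$nz)
  smooth <- features$smoothness
  knn <- attr(features, "knn")
  if (is.null(knn)) {
    knn <- knn_indices(xyz, min(attr(features, "params")$K %||% 20L, n))
  }
  order_ids <- withr::with_seed(params$rng_seed, sample.int(n))
  used <- logical(n)
  assignment <- integer(n)
  seeds <- list()
  cos_theta <- cos(params$theta * pi / 180)
  facet_id <- 0L
  r1_2 <- params$r1^2 * (1 + 1e-12)
  for (i in order_ids) {
    if (used[i]) next
    nb <- knn[i, ]
    cand <- nb[!used[nb]]
    seed <- if (length(cand)) cand[which.max(smooth[cand])] else i
    facet_id <- facet_id + 1L
    xs <- xyz[seed, ]
    ns <- normals[seed, ]
    free <- which(!used)
    diff <- t(xyz[free, , drop = FALSE]) - xs
    within <- colSums(diff^2) <= r1_2
    cosang <- abs(normals[free, , drop = FALSE] %*% ns)[, 1]
    plane_d <- abs(as.vector(crossprod(diff, ns)))
    grow <- free[within & cosang >= cos_theta - 1e-12 &
                   plane_d <= params$sigma1 * (1 + 1e-12)]
    grow <- union(seed, grow)
    assignment[grow] <- facet_id
    used[grow] <- TRUE
    seeds[[facet_id]] <- xs
  }
  # any point never captured becomes its own singleton facet
  left <- which(!used)
  for (i in left) {
    facet_id <- facet_id + 1L
    assignment[i] <- facet_id
    seeds[[facet_id]] <- xyz[i, ]
  }
  list(assignment = assignment, seeds = do.call(rbind, seeds))
}

#' Local K-means facet refinement
#'
#' Lloyd-style refinement restricted to a search sphere: each iteration
#' resets every point's best distance to infinity, then processes the seeds
#' in ascending facet id; every cloud point within `r2` of a seed whose
#' distance is `<=` the current best is (re)assigned to that seed, so on an
#' exact tie the later-processed seed wins and ties are deterministic.
#' Points captured by no sphere are assigned to their globally nearest
#' seed. Each cluster becomes a new facet and its seed moves to the member
#' mean. Iteration stops when the largest seed displacement drops below
#' `stability_tol` or after `max_kmeans_iters` rounds. A seed that loses
#' all members is dropped with a warning.
#'
#' @inheritParams coarse_facets
#' @param assignment integer facet id per point (from [coarse_facets()]).
#' @param seeds F x 3 matrix of seed coordinates.
#' @return A list: `assignment` (refined facet id per point, renumbered
#'   1..F'), `seeds` (final seed positions, the member means), and
#'   `iterations` used.
#' @export
local_kmeans_refine <- function(cloud, assignment, seeds,
                                params = overseg_params()) {
  check_cloud(cloud)
  n <- nrow(cloud)
  if (n == 0) {
    return(list(assignment = integer(),
                seeds = matrix(numeric(), ncol = 3), iterations = 0L))
  }
  if (is.null(seeds) || nrow(seeds) == 0) abort("`seeds` must be nonempty.")
  xyz <- cloud_xyz(cloud)
  r2_2 <- params$r2^2 * (1 + 1e-12)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    S <- nrow(seeds)
    di <- rep(Inf, n)
    assign_new <- rep(NA_integer_, n)
    d2 <- cross_dist2(seeds, xyz)  # S x n
    for (s in seq_len(S)) {
      row <- d2[s, ]
      upd <- which(row <= r2_2 & row <= di)
      di[upd] <- row[upd]
      assign_new[upd] <- s
    }
    orphan <- which(is.na(assign_new))
    if (length(orphan)) {
      assign_new[orphan] <- apply(d2[, orphan, drop = FALSE], 2, which.min)
    }
    sizes <- tabulate(assign_new, nbins = S)
    if (any(sizes == 0)) {
      warn(paste0(sum(sizes == 0), " facet seed(s) lost all members and ",
                  "were dropped."))
      keep <- which(sizes > 0)
      remap <- match(seq_len(S), keep)
      assign_new <- remap[assign_new]
      seeds <- seeds[keep, , drop = FALSE]
      S <- length(keep)
      sizes <- sizes[keep]
      dropped <- TRUE
    } else {
      dropped <- FALSE
    }
    new_seeds <- rowsum(xyz, assign_new) / sizes
    moved <- sqrt(max(rowSums((new_seeds - seeds)^2)))
    seeds <- new_seeds
    assignment <- assign_new
    if ((!dropped && moved < params$stability_tol) ||
        iterations >= params$max_kmeans_iters) {
      break
    }
  }
  dimnames(seeds) <- NULL
  list(assignment = as.integer(assignment), seeds = seeds,
       iterations = iterations)
}

#' Facet over-segmentation
#'
#' Full over-segmentation stage: coarse facet generation by seed selection
#' and three-condition region growing, followed by local K-means boundary
#' refinement. The refined facets partition the cloud.
#'
#' @inheritParams coarse_facets
#' @return An object of class `facet_set`: a list with `assignment` (tibble
#'   `id`, `facet_id`), `facets` (tibble `facet_id`, `size`, `seed_x`,
#'   `seed_y`, `seed_z`), `kmeans_iterations`, and `params`.
#' @examples
#' canopy <- synthetic_canopy(n_leaves = 2, points_per_leaf = 150,
#'                            ground = FALSE, pot = FALSE, n_outliers = 0,
#'                            rng_seed = 1)
#' feats <- compute_features(canopy, feature_params(K = 15))
#' fs <- oversegment(canopy, feats)
#' glance(fs)
#' @export
oversegment <- function(cloud, features, params = overseg_params()) {
  coarse <- coarse_facets(cloud, features, params)
  refined <- local_kmeans_refine(cloud, coarse$assignment, coarse$seeds,
                                 params)
  facet_set(cloud, refined$assignment, refined$seeds,
            kmeans_iterations = refined$iterations, params = params)
}

facet_set <- function(cloud, assignment, seeds, kmeans_iterations = 0L,
                      params = NULL) {
  n <- nrow(cloud)
  if (n == 0) {
    facets <- tibble(facet_id = integer(), size = integer(),
                     seed_x = numeric(), seed_y = numeric(),
                     seed_z = numeric())
    return(structure(list(assignment = tibble(id = integer(),
                                              facet_id = integer()),
                          facets = facets,
                          kmeans_iterations = kmeans_iterations,
                          params = params),
                     class = "facet_set"))
  }
  sizes <- tabulate(assignment, nbins = nrow(seeds))
  structure(list(
    assignment = tibble(id = seq_len(n), facet_id = as.integer(assignment)),
    facets = tibble(facet_id = seq_len(nrow(seeds)), size = sizes,
                    seed_x = seeds[, 1], seed_y = seeds[, 2],
                    seed_z = seeds[, 3]),
    kmeans_iterations = kmeans_iterations,
    params = params
  ), class = "facet_set")
}

#' @export
print.facet_set <- function(x, ...) {
  cat("Facet over-segmentation: ", nrow(x$facets), " facets over ",
      nrow(x$assignment), " points (",
      x$kmeans_iterations, " K-means iteration(s))\n", sep = "")
  print(utils::head(x$facets, 5))
  invisible(x)
}

#' @rdname oversegment
#' @param x a `facet_set`.
#' @param ... unused.
#' @method tidy facet_set
#' @export
tidy.facet_set <- function(x, ...) x$facets

#' @rdname oversegment
#' @method glance facet_set
#' @export
glance.facet_set <- function(x, ...) {
  tibble(n_facets = nrow(x$facets),
         n_points = nrow(x$assignment),
         mean_size = if (nrow(x$facets)) mean(x$facets$size) else NA_real_,
         kmeans_iterations = x$kmeans_iterations)
}

#' @rdname oversegment
#' @param object a `facet_set`.
#' @param cloud2 the cloud the facets were computed on (for point
#'   coordinates).
#' @method autoplot facet_set
#' @export
autoplot.facet_set <- function(object, cloud2, ...) {
  plot_cloud(cloud2, color = object$assignment$facet_id, ...)
}

#' Per-point facet labels of a facet set
#'
#' @param facets a `facet_set`.
#' @return Integer vector of facet ids in cloud point order.
#' @export
facet_labels <- function(facets) {
  stopifnot(inherits(facets, "facet_set"))
  facets$assignment$facet_id
}
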