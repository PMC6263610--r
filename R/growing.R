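#' Leaf-growing parameters
#'
#' @param sigma2 coplanarity threshold in meters: the distance from a
#'   candidate facet's center to the current facet's fitted plane must not
#'   exceed this for the candidate to merge. Default 0.0055 m (small curved
#'   leaves); use 0.0025 m for large flat leaves.
#' @param adjacency_eps facet adjacency tolerance in meters: two facets are
#'   adjacent when their closest member points are within this distance.
#'   `NULL` (default) means 1.5 times the median nearest-neighbor spacing
#'   of the cloud, adapting to its sampling density.
#' @param min_leaf_points a grown structure must cover at least this many
#'   points to count as a leaf; smaller ones go to the unassigned pool.
#'   Default 50.
#' @param symmetric also require the reverse coplanarity test
#'   `d(j, i) <= sigma2` before merging. Off by default: the pseudocode
#'   tests only the popped-facet-to-candidate direction.
#' @return A list of class `grow_params`.
#' @export
grow_params <- function(sigma2 = 0.0055, adjacency_eps = NULL,
                        min_leaf_points = 50, symmetric = FALSE) {
  stopifnot(sigma2 > 0, is.null(adjacency_eps) || adjacency_eps > 0,
            min_leaf_points >= 1)
  structure(list(sigma2 = sigma2, adjacency_eps = adjacency_eps,
                 min_leaf_points = as.integer(min_leaf_points),
                 symmetric = isTRUE(symmetric)),
            class = "grow_params")
}

#' Facet adjacency relation
#'
#' Two facets are adjacent iff the minimum pairwise distance between their
#' member points is at most `adjacency_eps`. The relation is symmetric and
#' irreflexive.
#'
#' @param facets a `facet_set` (or an integer facet label vector).
#' @param cloud the cloud the facets partition.
#' @param adjacency_eps adjacency tolerance in meters; `NULL` uses 1.5x the
#'   median nearest-neighbor spacing.
#' @return A tibble of adjacent unordered pairs (`facet_i` < `facet_j`).
#' @export
facet_adjacency <- function(facets, cloud, adjacency_eps = NULL) {
  check_cloud(cloud)
  labels <- if (inherits(facets, "facet_set")) facet_labels(facets) else
    as.integer(facets)
  if (length(labels) != nrow(cloud)) {
    abort("Facet labels are not aligned with the cloud.")
  }
  xyz <- cloud_xyz(cloud)
  if (is.null(adjacency_eps)) adjacency_eps <- default_adjacency_eps(xyz)
  pairs <- radius_pairs(xyz, adjacency_eps)
  fi <- labels[pairs[, 1]]
  fj <- labels[pairs[, 2]]
  keep <- fi != fj
  a <- pmin(fi[keep], fj[keep])
  b <- pmax(fi[keep], fj[keep])
  uniq <- !duplicated(cbind(a, b))
  tibble(facet_i = a[uniq], facet_j = b[uniq]) |>
    arrange(.data$facet_i, .data$facet_j)
}

default_adjacency_eps <- function(xyz) {
  if (nrow(xyz) < 2) return(Inf)
  1.5 * median(nn_spacing(xyz))
}

# PCA plane of a facet: centroid + unit normal (smallest eigenvector).
# Facets with < 3 members cannot fix a plane and are flagged degenerate;
# the center-to-center distance is used for them instead.
facet_plane <- function(xyz_members) {
  m <- nrow(xyz_members)
  centroid <- colMeans(xyz_members)
  if (m < 3) {
    return(list(centroid = centroid, normal = NULL, degenerate = TRUE))
  }
  Xc <- t(xyz_members) - centroid
  ev <- eigen(tcrossprod(Xc) / m, symmetric = TRUE)
  list(centroid = centroid, normal = canonicalize_normal(ev$vectors[, 3]),
       degenerate = FALSE)
}

#' Center-to-plane distance between two facets
#'
#' Fits a plane to facet `i`'s member points by PCA and returns the
#' distance from facet `j`'s center (member centroid) to that plane. For a
#' facet with fewer than three members no plane exists; the centroid-to-
#' centroid distance is returned and flagged via the `"degenerate"`
#' attribute.
#'
#' @param facets a `facet_set`.
#' @param cloud the matching cloud.
#' @param i,j facet ids.
#' @return Distance in meters (attribute `degenerate` = TRUE for the
#'   fallback).
#' @export
facet_plane_distance <- function(facets, cloud, i, j) {
  stopifnot(inherits(facets, "facet_set"))
  labels <- facet_labels(facets)
  xyz <- cloud_xyz(cloud)
  pi_ <- facet_plane(xyz[labels == i, , drop = FALSE])
  cj <- colMeans(xyz[labels == j, , drop = FALSE])
  if (pi_$degenerate) {
    structure(sqrt(sum((cj - pi_$centroid)^2)), degenerate = TRUE)
  } else {
    structure(point_plane_distance(pi_$normal, pi_$centroid, cj),
              degenerate = FALSE)
  }
}

#' Breadth-first facet region growing into leaves
#'
#' Merges facets into individual leaves. Facets are visited in ascending
#' facet id; each still-unused facet starts a new leaf and a breadth-first
#' queue. When facet `i` is popped, every unused facet `j` that is (a)
#' adjacent to `i` and (b) coplanar with it -- the distance from `j`'s
#' center to `i`'s fitted plane is at most `sigma2` -- joins the leaf and
#' is enqueued. The plane of `i` is fit from `i`'s own members only, not
#' the accumulated leaf. After growing, structures covering fewer than
#' `min_leaf_points` points are moved to the unassigned pool (label `-1`)
#' and reported in `discarded`.
#'
#' @param facets a `facet_set` from [oversegment()].
#' @param cloud the matching cloud.
#' @param params a [grow_params()] object.
#' @return An object of class `leaf_segmentation`: a list with `labels`
#'   (tibble `id`, `leaf_id`; `-1` = unassigned), `leaves` (tibble
#'   `leaf_id`, `n_facets`, `n_points`, centroid columns), `facet_map`
#'   (tibble `facet_id`, `leaf_id`, `round` -- the BFS wave on which the
#'   facet joined, 0 for the starting facet), `discarded` (same shape as
#'   `leaves`, structures below the size cut), `adjacency`, and `params`.
#' @examples
#' canopy <- synthetic_canopy(n_leaves = 2, points_per_leaf = 150,
#'                            ground = FALSE, pot = FALSE, n_outliers = 0,
#'                            rng_seed = 1)
#' feats <- compute_features(canopy, feature_params(K = 15))
#' fs <- oversegment(canopy, feats)
#' leaves <- grow_leaves(fs, canopy)
#' glance(leaves)
#' @export
grow_leaves <- function(facets, cloud, params = grow_params()) {
  stopifnot(inherits(facets, "facet_set"), inherits(params, "grow_params"))
  check_cloud(cloud)
  labels <- facet_labels(facets)
  n_f <- nrow(facets$facets)
  xyz <- cloud_xyz(cloud)
  adj_tbl <- facet_adjacency(facets, cloud, params$adjacency_eps)
  adj <- vector("list", n_f)
  for (r in seq_len(nrow(adj_tbl))) {
    a <- adj_tbl$facet_i[r]
    b <- adj_tbl$facet_j[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  members <- split(seq_along(labels), labels)
  planes <- lapply(seq_len(n_f), function(f) {
    facet_plane(xyz[members[[as.character(f)]], , drop = FALSE])
  })
  pair_ok <- function(i, j) {
    pi_ <- planes[[i]]
    cj <- planes[[j]]$centroid
    d <- if (pi_$degenerate) {
      sqrt(sum((cj - pi_$centroid)^2))
    } else {
      abs(sum(pi_$normal * (cj - pi_$centroid)))
    }
    if (d > params$sigma2) return(FALSE)
    if (params$symmetric) {
      pj <- planes[[j]]
      ci <- pi_$centroid
      d2 <- if (pj$degenerate) {
        sqrt(sum((ci - pj$centroid)^2))
      } else {
        abs(sum(pj$normal * (ci - pj$centroid)))
      }
      if (d2 > params$sigma2) return(FALSE)
    }
    TRUE
  }
  used <- logical(n_f)
  leaf_of <- integer(n_f)
  round_of <- integer(n_f)
  n_leaves <- 0L
  for (f0 in seq_len(n_f)) {
    if (used[f0]) next
    n_leaves <- n_leaves + 1L
    queue <- f0
    used[f0] <- TRUE
    leaf_of[f0] <- n_leaves
    round_of[f0] <- 0L
    while (length(queue)) {
      fi <- queue[1]
      queue <- queue[-1]
      for (fj in sort(adj[[fi]])) {
        if (used[fj]) next
        if (pair_ok(fi, fj)) {
          used[fj] <- TRUE
          leaf_of[fj] <- n_leaves
          round_of[fj] <- round_of[fi] + 1L
          queue <- c(queue, fj)
        }
      }
    }
  }
  point_leaf <- leaf_of[labels]
  leaf_sizes <- tabulate(point_leaf, nbins = n_leaves)
  keep_leaf <- leaf_sizes >= params$min_leaf_points
  # renumber surviving leaves 1..L in first-appearance order
  new_id <- integer(n_leaves)
  new_id[keep_leaf] <- seq_len(sum(keep_leaf))
  final_point <- ifelse(keep_leaf[point_leaf], new_id[point_leaf], -1L)
  leaf_summary <- function(ids) {
    purrr::map_dfr(ids, function(l) {
      fs <- which(leaf_of == l)
      pts <- which(point_leaf == l)
      tibble(n_facets = length(fs), n_points = length(pts),
             centroid_x = mean(xyz[pts, 1]), centroid_y = mean(xyz[pts, 2]),
             centroid_z = mean(xyz[pts, 3]))
    })
  }
  kept_ids <- which(keep_leaf)
  leaves <- leaf_summary(kept_ids)
  if (nrow(leaves)) leaves <- tibble(leaf_id = new_id[kept_ids], leaves)
  else leaves <- tibble(leaf_id = integer(), n_facets = integer(),
                        n_points = integer(), centroid_x = numeric(),
                        centroid_y = numeric(), centroid_z = numeric())
  disc_ids <- which(!keep_leaf)
  discarded <- leaf_summary(disc_ids)
  if (nrow(discarded)) discarded <- tibble(leaf_id = -1L, discarded)
  else discarded <- leaves[0, ]
  structure(list(
    labels = tibble(id = seq_along(final_point),
                    leaf_id = as.integer(final_point)),
    leaves = leaves,
    facet_map = tibble(facet_id = seq_len(n_f),
                       leaf_id = ifelse(keep_leaf[leaf_of],
                                        new_id[leaf_of], -1L),
                       round = round_of),
    discarded = discarded,
    adjacency = adj_tbl,
    params = params
  ), class = "leaf_segmentation")
}

#' @export
print.leaf_segmentation <- function(x, ...) {
  cat("Leaf segmentation: ", nrow(x$leaves), " leaves over ",
      nrow(x$labels), " points (",
      sum(x$labels$leaf_id < 0), " unassigned)\n", sep = "")
  print(x$leaves)
  invisible(x)
}

#' @rdname grow_leaves
#' @param x,object a `leaf_segmentation`.
#' @param ... unused.
#' @method tidy leaf_segmentation
#' @export
tidy.leaf_segmentation <- function(x, ...) x$leaves

#' @rdname grow_leaves
#' @method glance leaf_segmentation
#' @export
glance.leaf_segmentation <- function(x, ...) {
  tibble(n_leaves = nrow(x$leaves),
         n_points = nrow(x$labels),
         n_unassigned = sum(x$labels$leaf_id < 0),
         n_discarded_structures = nrow(x$discarded))
}

#' @rdname grow_leaves
#' @param cloud2 the cloud the segmentation was computed on.
#' @method autoplot leaf_segmentation
#' @export
autoplot.leaf_segmentation <- function(object, cloud2, ...) {
  plot_cloud(cloud2, color = object$labels$leaf_id, ...)
}

#' Per-point leaf labels of a segmentation
#'
#' @param leaves a `leaf_segmentation`.
#' @return Integer vector of leaf ids in cloud point order; `-1` means
#'   unassigned.
#' @export
leaf_labels <- function(leaves) {
  stopifnot(inherits(leaves, "leaf_segmentation"))
  leaves$labels$leaf_id
}
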