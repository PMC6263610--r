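#' Ground (z-axis) filter
#'
#' Keeps points at or above a ground cut `z_min`; everything strictly below
#' is treated as ground/pot clutter. The boundary is inclusive: `z == z_min`
#' survives. Relative point order is preserved.
#'
#' @param cloud a point cloud tibble.
#' @param z_min ground cut in meters.
#' @return The filtered cloud (a subset of the input rows).
#' @export
filter_zaxis <- function(cloud, z_min) {
  check_cloud(cloud)
  cloud_subset(cloud, cloud$z >= z_min)
}

#' Excess-green vegetation filter
#'
#' Keeps points whose excess-green index `ExG = 2G - R - B` (colors on the
#' 0--1 scale) strictly exceeds `threshold`. ExG ranges over `[-2, 2]`; pure
#' green scores 2, achromatic points score 0.
#'
#' @inheritParams filter_zaxis
#' @param threshold dimensionless ExG cut.
#' @return The filtered cloud.
#' @export
filter_greenness <- function(cloud, threshold) {
  check_cloud(cloud)
  if (!has_colors(cloud)) {
    abort(paste("Cloud has no colors; the greenness filter needs RGB.",
                "Disable this filter for colorless clouds."))
  }
  exg <- 2 * cloud$g - cloud$r - cloud$b
  cloud_subset(cloud, exg > threshold)
}

#' Radius outlier filter
#'
#' A point survives iff at least `min_neighbors` OTHER points lie within the
#' closed ball of radius `radius` around it. All decisions are made against
#' the input cloud, not incrementally against a partially filtered one.
#'
#' @inheritParams filter_zaxis
#' @param radius search-sphere radius in meters (the radius `r`).
#' @param min_neighbors minimum neighbor count (the threshold `n1`).
#' @return The filtered cloud.
#' @export
filter_radius_outliers <- function(cloud, radius, min_neighbors) {
  check_cloud(cloud)
  stopifnot(radius > 0, min_neighbors >= 1)
  if (nrow(cloud) == 0) return(cloud)
  cnt <- radius_counts(cloud_xyz(cloud), radius)
  cloud_subset(cloud, cnt >= min_neighbors)
}

#' Statistical outlier filter
#'
#' For each point, the mean distance \eqn{d_i} to its `k` nearest neighbors
#' is computed; with \eqn{\mu} and \eqn{\sigma} the mean and standard
#' deviation of all \eqn{d_i}, a point survives iff
#' \eqn{d_i \le \mu + n_2 \sigma}. This is the neighborhood-spacing rule of
#' PCL's StatisticalOutlierRemoval: whole points are removed, in one pass
#' over the input cloud.
#'
#' @inheritParams filter_zaxis
#' @param k neighborhood size for the mean-spacing estimate.
#' @param std_mult standard-deviation multiplier (the coefficient `n2`).
#' @return The filtered cloud.
#' @export
filter_statistical_outliers <- function(cloud, k, std_mult) {
  check_cloud(cloud)
  stopifnot(k >= 1, std_mult >= 0)
  if (nrow(cloud) == 0) return(cloud)
  if (nrow(cloud) <= k) {
    abort(paste0("Statistical filter needs more than k = ", k,
                 " points; cloud has ", nrow(cloud), "."))
  }
  d <- knn_mean_dist(cloud_xyz(cloud), k)
  bound <- mean(d) + std_mult * sd(d)
  cloud_subset(cloud, d <= bound + 1e-12)
}

#' Default preprocessing parameters
#'
#' Bundles the parameters of the four cleaning filters. `enabled` selects
#' which filters run (in the fixed order z-axis, greenness, radius,
#' statistical). Defaults follow the dense small-leaf regime: all four
#' filters on, `radius = 0.015` m with 85 required neighbors, `k = 40`
#' neighbors and one standard deviation for the spacing rule. `z_min` and
#' the ExG threshold are package conventions (the ground height and color
#' calibration are scene properties); tune them per scene.
#'
#' @param z_min ground cut, meters.
#' @param greenness ExG threshold, dimensionless.
#' @param radius radius-filter sphere radius, meters.
#' @param min_neighbors radius-filter neighbor threshold.
#' @param k statistical-filter neighborhood size.
#' @param std_mult statistical-filter standard-deviation multiplier.
#' @param enabled character subset of
#'   `c("zaxis", "greenness", "radius", "statistical")`.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(z_min = 0.2, greenness = 0.1,
                          radius = 0.015, min_neighbors = 85,
                          k = 40, std_mult = 1,
                          enabled = c("zaxis", "greenness", "radius",
                                      "statistical")) {
  stopifnot(radius > 0, min_neighbors >= 1, k >= 1, std_mult >= 0)
  bad <- setdiff(enabled, c("zaxis", "greenness", "radius", "statistical"))
  if (length(bad)) abort(paste0("Unknown filter name(s): ",
                                paste(bad, collapse = ", ")))
  structure(list(z_min = z_min, greenness = greenness, radius = radius,
                 min_neighbors = min_neighbors, k = k, std_mult = std_mult,
                 enabled = enabled),
            class = "filter_params")
}

#' Run the preprocessing pipeline
#'
#' Applies the enabled filters in the fixed order z-axis, greenness, radius
#' outlier, statistical outlier; each filter sees the previous filter's
#' output. The returned cloud carries a per-filter removal log in its
#' `"filter_log"` attribute (also retrievable via [filter_log()]).
#'
#' @inheritParams filter_zaxis
#' @param params a [filter_params()] object.
#' @return The filtered cloud, with attribute `filter_log`: a tibble with
#'   one row per applied filter (`filter`, `n_in`, `n_out`, `n_removed`).
#' @examples
#' canopy <- synthetic_canopy(n_leaves = 2, points_per_leaf = 120,
#'                            rng_seed = 1)
#' clean <- preprocess_cloud(canopy, filter_params(min_neighbors = 10))
#' filter_log(clean)
#' @export
preprocess_cloud <- function(cloud, params = filter_params()) {
  check_cloud(cloud)
  stopifnot(inherits(params, "filter_params"))
  log <- list()
  apply_one <- function(cl, name, fun) {
    n_in <- nrow(cl)
    out <- fun(cl)
    log[[name]] <<- tibble(filter = name, n_in = n_in, n_out = nrow(out),
                           n_removed = n_in - nrow(out))
    out
  }
  out <- cloud
  if ("zaxis" %in% params$enabled) {
    out <- apply_one(out, "zaxis", function(cl) filter_zaxis(cl, params$z_min))
  }
  if ("greenness" %in% params$enabled) {
    out <- apply_one(out, "greenness",
                     function(cl) filter_greenness(cl, params$greenness))
  }
  if ("radius" %in% params$enabled) {
    out <- apply_one(out, "radius", function(cl) {
      filter_radius_outliers(cl, params$radius, params$min_neighbors)
    })
  }
  if ("statistical" %in% params$enabled) {
    out <- apply_one(out, "statistical", function(cl) {
      filter_statistical_outliers(cl, params$k, params$std_mult)
    })
  }
  attr(out, "filter_log") <- if (length(log)) {
    bind_rows(log)
  } else {
    tibble(filter = character(), n_in = integer(), n_out = integer(),
           n_removed = integer())
  }
  out
}

#' @rdname preprocess_cloud
#' @param filtered a cloud returned by `preprocess_cloud()`.
#' @export
filter_log <- function(filtered) {
  attr(filtered, "filter_log") %||%
    tibble(filter = character(), n_in = integer(), n_out = integer(),
           n_removed = integer())
}
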