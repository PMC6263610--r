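#' Construct a point cloud tibble
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (coordinates in meters) and, when per-point color is available, `r`, `g`,
#' `b` normalized to `[0, 1]`. Row order is meaningful: row `i` is point `i`,
#' and every per-point result in the package (features, facet labels, leaf
#' labels) is aligned to it. The original color dialect of a file
#' (`"uchar255"` 0--255 integers or `"float01"` floats) is kept in the
#' `color_dialect` attribute so [write_cloud()] can write colors back on the
#' scale they came in.
#'
#' @param points numeric matrix or data frame with three columns (x, y, z).
#' @param colors optional numeric matrix or data frame with three columns
#'   (red, green, blue), either 0--255 or 0--1; same number of rows as
#'   `points`.
#' @param color_dialect `"auto"` (detect from the value range), `"uchar255"`
#'   or `"float01"`.
#'
#' @return A tibble with columns `x`, `y`, `z` and optionally `r`, `g`, `b`
#'   (always stored in `[0, 1]`).
#' @examples
#' pc <- point_cloud(matrix(runif(30), ncol = 3))
#' nrow(pc)
#' @export
point_cloud <- function(points, colors = NULL, color_dialect = "auto") {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(), ncol = 3)
  if (ncol(points) != 3) {
    abort("`points` must have exactly three columns (x, y, z).")
  }
  storage.mode(points) <- "double"
  if (nrow(points) > 0 && !all(is.finite(points))) {
    abort("All point coordinates must be finite.")
  }
  cloud <- tibble(x = points[, 1], y = points[, 2], z = points[, 3])
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "double"
    if (nrow(colors) != nrow(points) || ncol(colors) != 3) {
      abort("`colors` must be an N x 3 matrix matching `points`.")
    }
    if (identical(color_dialect, "auto")) {
      color_dialect <- if (nrow(colors) > 0 && max(colors) > 1 + 1e-9) {
        "uchar255"
      } else {
        "float01"
      }
    }
    if (color_dialect == "uchar255") colors <- colors / 255
    cloud$r <- colors[, 1]
    cloud$g <- colors[, 2]
    cloud$b <- colors[, 3]
    attr(cloud, "color_dialect") <- color_dialect
  }
  cloud
}

#' Extract the coordinate matrix of a cloud
#'
#' @param cloud a point cloud tibble (or any data frame with `x`, `y`, `z`).
#' @return An N x 3 double matrix.
#' @export
cloud_xyz <- function(cloud) {
  check_cloud(cloud)
  cbind(x = as.double(cloud$x), y = as.double(cloud$y), z = as.double(cloud$z))
}

#' Does a cloud carry per-point color?
#'
#' @inheritParams cloud_xyz
#' @return `TRUE` if `r`, `g`, `b` columns are all present.
#' @export
has_colors <- function(cloud) {
  all(c("r", "g", "b") %in% names(cloud))
}

check_cloud <- function(cloud) {
  if (!is.data.frame(cloud) || !all(c("x", "y", "z") %in% names(cloud))) {
    abort("Expected a point cloud: a data frame with columns x, y, z.")
  }
  invisible(cloud)
}

# Keep a subset of rows while preserving cloud attributes (color dialect).
cloud_subset <- function(cloud, keep) {
  out <- cloud[keep, , drop = FALSE]
  attr(out, "color_dialect") <- attr(cloud, "color_dialect")
  out
}

#' Plot a point cloud projection
#'
#' Projects the cloud onto a coordinate plane and draws the points,
#' optionally colored by a per-point grouping (facet or leaf labels).
#'
#' @inheritParams cloud_xyz
#' @param color optional vector (length N) used as a discrete color
#'   aesthetic; label `-1` is shown in grey as "unassigned".
#' @param axes which two coordinates to plot, e.g. `c("x", "y")`.
#' @param point_size passed to [ggplot2::geom_point()].
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, color = NULL, axes = c("x", "y"),
                       point_size = 0.6) {
  check_cloud(cloud)
  df <- as_tibble(cloud[, axes])
  names(df) <- c("u", "v")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v))
  if (is.null(color)) {
    p <- p + ggplot2::geom_point(size = point_size)
  } else {
    lab <- ifelse(color < 0, NA_character_, as.character(color))
    df$group <- factor(lab)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                          colour = .data$group)) +
      ggplot2::geom_point(size = point_size, show.legend = FALSE) +
      ggplot2::scale_colour_discrete(na.value = "grey70")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = axes[1], y = axes[2]) +
    ggplot2::theme_minimal()
}
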