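#' Sample one synthetic curved leaf
#'
#' Samples a bent elliptical patch at roughly uniform density: a jittered
#' grid of pitch `spacing` over an ellipse footprint whose area is
#' `points_per_leaf * spacing^2` (so the sample count comes out near
#' `points_per_leaf`), lifted by the height field
#' `h(u, v) = curvature * (u^2 + v^2)` and rigidly moved by `pose`.
#' Analytic surface normals (the normalized gradient
#' `(-2cu, -2cv, 1)`) are returned alongside the points for validating
#' normal estimators.
#'
#' @param points_per_leaf target number of points on the leaf (default 450,
#'   the 400--500 per-leaf density of dense greenhouse scans).
#' @param spacing target nearest-neighbor spacing in meters (default
#'   0.002, i.e. ~2 mm dense-scan spacing).
#' @param curvature bending amplitude of the paraboloid height field in
#'   1/m; 0 gives an exactly planar leaf.
#' @param aspect ellipse aspect ratio (semi-major / semi-minor).
#' @param jitter in-plane jitter as a fraction of `spacing`.
#' @param pose list with rotation matrix `R` (3 x 3) and translation `t`
#'   (length 3); `NULL` = identity.
#' @param rng_seed integer seed; the same seed gives bit-identical output.
#'   `NULL` uses the current RNG state (for callers that manage seeding).
#' @return A tibble with columns `x`, `y`, `z`, `nx`, `ny`, `nz`.
#' @examples
#' leaf <- synthetic_leaf(points_per_leaf = 100, rng_seed = 1)
#' nrow(leaf)
#' @export
synthetic_leaf <- function(points_per_leaf = 450, spacing = 0.002,
                           curvature = 4, aspect = 1.6, jitter = 0.3,
                           pose = NULL, rng_seed = 0) {
  stopifnot(points_per_leaf >= 1, spacing > 0, aspect >= 1, jitter >= 0)
  gen <- function() {
    area <- points_per_leaf * spacing^2
    b <- sqrt(area / (pi * aspect))
    a <- aspect * b
    u <- seq(-a, a, by = spacing)
    v <- seq(-b, b, by = spacing)
    grid <- expand.grid(u = u, v = v)
    keep <- (grid$u / a)^2 + (grid$v / b)^2 <= 1
    grid <- grid[keep, , drop = FALSE]
    m <- nrow(grid)
    gu <- grid$u + stats::runif(m, -jitter, jitter) * spacing
    gv <- grid$v + stats::runif(m, -jitter, jitter) * spacing
    h <- curvature * (gu^2 + gv^2)
    pts <- cbind(gu, gv, h)
    nrm <- cbind(-2 * curvature * gu, -2 * curvature * gv, rep(1, m))
    nrm <- nrm / sqrt(rowSums(nrm^2))
    if (!is.null(pose)) {
      pts <- t(pose$R %*% t(pts) + pose$t)
      nrm <- t(pose$R %*% t(nrm))
    }
    tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
           nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
  }
  if (is.null(rng_seed)) gen() else withr::with_seed(rng_seed, gen())
}

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

leaf_bound_radius <- function(points_per_leaf, spacing, curvature, aspect) {
  area <- points_per_leaf * spacing^2
  b <- sqrt(area / (pi * aspect))
  a <- aspect * b
  sqrt(a^2 + (curvature * a^2)^2)
}

#' Generate a labelled synthetic plant canopy
#'
#' Builds a complete labelled test scene: `n_leaves` curved leaves arranged
#' in a ring at canopy height with a guaranteed pairwise surface gap of at
#' least `min_leaf_gap`, an optional ground plane below, an optional pot
#' cylinder, and sparse isolated outlier points. A chosen fraction of leaf
#' pairs can instead be placed *coplanar and adjacent* (the classic failure
#' mode of coplanarity-based merging): those pairs are flat, share a plane,
#' and sit within `occlusion_gap` of each other; a small number of blended
#' boundary points between them emulates sensor boundary interpolation.
#'
#' Every point carries a ground-truth `label` (leaf index 1..n, `-1` for
#' non-leaf), a component `tag` (`"leaf"`, `"ground"`, `"pot"`,
#' `"outlier"`, `"noise"`), and -- for leaf points -- the analytic surface
#' normal (`nx`, `ny`, `nz`). The tibble is itself a valid colored point
#' cloud, so it feeds directly into [preprocess_cloud()] and the rest of
#' the pipeline; because per-point metadata lives in columns, any filtering
#' keeps labels aligned automatically.
#'
#' @param n_leaves number of leaves (default 8).
#' @inheritParams synthetic_leaf
#' @param min_leaf_gap minimum surface-to-surface gap between non-occluded
#'   leaves, meters (default 0.03, several times the coplanarity threshold
#'   of the growing stage so separated leaves can never merge).
#' @param max_tilt maximum random tilt of a leaf from horizontal, degrees.
#' @param canopy_z canopy center height above the ground plane, meters.
#' @param n_outliers number of isolated outlier points; they are placed at
#'   least `outlier_clearance` from every structure point and at least
#'   2.3 cm from each other, so a radius filter can remove them all.
#' @param outlier_clearance minimum distance of an outlier to the rest of
#'   the scene, meters.
#' @param ground add a jittered ground plane at z = 0 (`ground_spacing`
#'   pitch)?
#' @param pot add a pot cylinder under the canopy?
#' @param ground_spacing,pot_spacing sampling pitch of ground and pot.
#' @param occlusion_fraction fraction of leaf pairs forced into the
#'   coplanar-adjacent hard case (0 = none).
#' @param occlusion_gap in-plane edge gap of an occluded pair, meters.
#' @param boundary_noise number of blended boundary points added between
#'   the two leaves of each occluded pair (tag `"noise"`, label `-1`).
#' @param rng_seed integer seed; generation is deterministic given it.
#' @return A tibble with columns `x`, `y`, `z`, `r`, `g`, `b`, `label`,
#'   `tag`, `nx`, `ny`, `nz`.
#' @examples
#' canopy <- synthetic_canopy(n_leaves = 3, points_per_leaf = 100,
#'                            rng_seed = 1)
#' dplyr::count(canopy, tag)
#' @export
synthetic_canopy <- function(n_leaves = 8, points_per_leaf = 450,
                             spacing = 0.002, curvature = 4, aspect = 1.6,
                             min_leaf_gap = 0.03, max_tilt = 20,
                             canopy_z = 0.3,
                             n_outliers = 20, outlier_clearance = 0.05,
                             ground = TRUE, ground_spacing = 0.01,
                             pot = TRUE, pot_spacing = 0.008,
                             occlusion_fraction = 0, occlusion_gap = 0.001,
                             boundary_noise = 8, rng_seed = 0) {
  stopifnot(n_leaves >= 0, points_per_leaf >= 1, spacing > 0,
            min_leaf_gap > 0, occlusion_fraction >= 0,
            occlusion_fraction <= 1, n_outliers >= 0)
  withr::with_seed(rng_seed, {
    rho <- leaf_bound_radius(points_per_leaf, spacing, curvature, aspect)
    parts <- list()
    # --- leaves on a ring, adjacent chord >= 2 rho + gap ------------------
    if (n_leaves > 0) {
      n_occl_pairs <- floor(occlusion_fraction * n_leaves / 2)
      occl_follower <- rep(FALSE, n_leaves)
      if (n_occl_pairs > 0) occl_follower[2 * seq_len(n_occl_pairs)] <- TRUE
      chord <- 2 * rho + min_leaf_gap
      ring_r <- if (n_leaves > 1) chord / (2 * sin(pi / n_leaves)) else 0
      poses <- vector("list", n_leaves)
      curvatures <- rep(curvature, n_leaves)
      for (i in seq_len(n_leaves)) {
        in_pair <- n_occl_pairs > 0 && i <= 2 * n_occl_pairs
        if (in_pair) curvatures[i] <- 0  # hard-case pairs are exactly flat
        if (occl_follower[i]) {
          lead <- poses[[i - 1]]
          area <- points_per_leaf * spacing^2
          a <- aspect * sqrt(area / (pi * aspect))
          offset <- lead$R %*% c(2 * a + occlusion_gap, 0, 0)
          poses[[i]] <- list(R = lead$R, t = lead$t + as.vector(offset))
        } else {
          ang <- 2 * pi * (i - 1) / n_leaves
          tilt <- if (in_pair) 0 else
            stats::runif(1, 0, max_tilt) * pi / 180
          yaw <- stats::runif(1, 0, 2 * pi)
          R <- rot_z(yaw) %*% rot_x(tilt)
          t <- c(ring_r * cos(ang), ring_r * sin(ang),
                 canopy_z + stats::runif(1, -0.02, 0.02))
          poses[[i]] <- list(R = R, t = t)
        }
      }
      for (i in seq_len(n_leaves)) {
        leaf <- synthetic_leaf(points_per_leaf, spacing, curvatures[i],
                               aspect, pose = poses[[i]], rng_seed = NULL)
        m <- nrow(leaf)
        leaf$r <- stats::runif(m, 0.05, 0.20)
        leaf$g <- stats::runif(m, 0.55, 0.85)
        leaf$b <- stats::runif(m, 0.05, 0.20)
        leaf$label <- i
        leaf$tag <- "leaf"
        parts[[length(parts) + 1]] <- leaf
      }
      # blended boundary points between occluded pair members
      if (n_occl_pairs > 0 && boundary_noise > 0) {
        for (p in seq_len(n_occl_pairs)) {
          la <- parts[[2 * p - 1]]
          lb <- parts[[2 * p]]
          A <- cbind(la$x, la$y, la$z)
          B <- cbind(lb$x, lb$y, lb$z)
          d2 <- cross_dist2(A, B)
          near <- arrayInd(order(d2)[seq_len(boundary_noise)], dim(d2))
          alpha <- stats::runif(boundary_noise, 0.25, 0.75)
          blend <- A[near[, 1], , drop = FALSE] * alpha +
            B[near[, 2], , drop = FALSE] * (1 - alpha)
          parts[[length(parts) + 1]] <- tibble(
            x = blend[, 1], y = blend[, 2], z = blend[, 3],
            nx = NA_real_, ny = NA_real_, nz = NA_real_,
            r = stats::runif(boundary_noise, 0.05, 0.20),
            g = stats::runif(boundary_noise, 0.55, 0.85),
            b = stats::runif(boundary_noise, 0.05, 0.20),
            label = -1L, tag = "noise")
        }
      }
    }
    leaf_pts <- if (length(parts)) {
      do.call(rbind, lapply(parts, function(p) cbind(p$x, p$y, p$z)))
    } else {
      matrix(numeric(), ncol = 3)
    }
    ext <- if (nrow(leaf_pts)) max(abs(leaf_pts[, 1:2])) + 0.05 else 0.2
    # --- ground plane ------------------------------------------------------
    if (ground) {
      gseq <- seq(-ext, ext, by = ground_spacing)
      gg <- expand.grid(x = gseq, y = gseq)
      m <- nrow(gg)
      parts[[length(parts) + 1]] <- tibble(
        x = gg$x + stats::runif(m, -0.3, 0.3) * ground_spacing,
        y = gg$y + stats::runif(m, -0.3, 0.3) * ground_spacing,
        z = stats::runif(m, 0, 0.002),
        nx = NA_real_, ny = NA_real_, nz = NA_real_,
        r = stats::runif(m, 0.35, 0.45), g = stats::runif(m, 0.25, 0.35),
        b = stats::runif(m, 0.15, 0.25),
        label = -1L, tag = "ground")
    }
    # --- pot cylinder ------------------------------------------------------
    if (pot) {
      pot_r <- 0.05
      pot_h <- 0.12
      n_ring <- max(8L, round(2 * pi * pot_r / pot_spacing))
      zs <- seq(0.005, pot_h, by = pot_spacing)
      ang <- rep(2 * pi * seq_len(n_ring) / n_ring, times = length(zs))
      zz <- rep(zs, each = n_ring)
      m <- length(ang)
      ang <- ang + stats::runif(m, -0.5, 0.5) * pot_spacing / pot_r
      parts[[length(parts) + 1]] <- tibble(
        x = pot_r * cos(ang), y = pot_r * sin(ang),
        z = zz + stats::runif(m, -0.3, 0.3) * pot_spacing,
        nx = NA_real_, ny = NA_real_, nz = NA_real_,
        r = stats::runif(m, 0.55, 0.65), g = stats::runif(m, 0.30, 0.40),
        b = stats::runif(m, 0.20, 0.30),
        label = -1L, tag = "pot")
    }
    scene <- if (length(parts)) bind_rows(parts) else
      tibble(x = numeric(), y = numeric(), z = numeric(),
             nx = numeric(), ny = numeric(), nz = numeric(),
             r = numeric(), g = numeric(), b = numeric(),
             label = integer(), tag = character())
    # --- isolated outliers -------------------------------------------------
    if (n_outliers > 0) {
      structure_xyz <- cbind(scene$x, scene$y, scene$z)
      placed <- matrix(numeric(), ncol = 3)
      tries <- 0L
      lo <- c(-ext - 0.1, -ext - 0.1, 0.02)
      hi <- c(ext + 0.1, ext + 0.1, canopy_z + 0.15)
      while (nrow(placed) < n_outliers && tries < 200L * n_outliers) {
        tries <- tries + 1L
        cand <- stats::runif(3, lo, hi)
        ok <- TRUE
        if (nrow(structure_xyz) &&
            min(cross_dist2(matrix(cand, 1), structure_xyz)) <
              outlier_clearance^2) {
          ok <- FALSE
        }
        if (ok && nrow(placed) &&
            min(cross_dist2(matrix(cand, 1), placed)) < 0.035^2) {
          ok <- FALSE
        }
        if (ok) placed <- rbind(placed, cand)
      }
      if (nrow(placed) < n_outliers) {
        abort(paste0("Could not place all outliers: ", nrow(placed),
                     " of ", n_outliers, " fit in the scene box."))
      }
      m <- nrow(placed)
      scene <- bind_rows(scene, tibble(
        x = placed[, 1], y = placed[, 2], z = placed[, 3],
        nx = NA_real_, ny = NA_real_, nz = NA_real_,
        r = stats::runif(m, 0.45, 0.55), g = stats::runif(m, 0.45, 0.55),
        b = stats::runif(m, 0.45, 0.55),
        label = -1L, tag = "outlier"))
    }
    scene$label <- as.integer(scene$label)
    attr(scene, "color_dialect") <- "float01"
    scene
  })
}
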