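#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects into one configuration. The
#' point-to-plane threshold `sigma1` is shared between the feature and
#' over-segmentation stages; [pipeline_config()] enforces that they agree.
#'
#' @param filter a [filter_params()] object.
#' @param features a [feature_params()] object.
#' @param overseg an [overseg_params()] object.
#' @param grow a [grow_params()] object.
#' @param profile optional profile name carried along for reporting.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_params(),
                            features = feature_params(),
                            overseg = overseg_params(),
                            grow = grow_params(),
                            profile = "custom") {
  stopifnot(inherits(filter, "filter_params"),
            inherits(features, "feature_params"),
            inherits(overseg, "overseg_params"),
            inherits(grow, "grow_params"))
  if (abs(features$sigma1 - overseg$sigma1) > 1e-12) {
    abort("`sigma1` must agree between the feature and over-segmentation stages.")
  }
  structure(list(filter = filter, features = features, overseg = overseg,
                 grow = grow, profile = profile),
            class = "pipeline_config")
}

#' Named parameter profiles
#'
#' Three ready-made configurations for the plant types the method was
#' developed on:
#' * `"epipremnum"` -- small curved leaves, crowded canopy: all four
#'   filters (radius `r = 0.015` m with `n1 = 85`, statistical `k = 40`,
#'   `n2 = 1`), `K = 20`, `sigma2 = 0.0055` m.
#' * `"monstera"` -- large broad leaves: z-axis + statistical filter only
#'   (`k = 25`, `n2 = 0.1`), `K = 40`, `sigma2 = 0.0025` m.
#' * `"makoyana"` -- large regular leaves: z-axis + radius filter only
#'   (`r = 0.015` m, `n1 = 50`), `K = 40`, `sigma2 = 0.0055` m.
#'
#' All three share `r1 = 0.03` m, `theta = 23` degrees, `sigma1 = 0.025` m
#' and `r2 = 0.1` m. The ground cut `z_min` and the ExG threshold are
#' scene properties with package-convention defaults; override them for
#' your scene.
#'
#' @param name profile name.
#' @param z_min,greenness scene-dependent overrides for the ground cut and
#'   ExG threshold.
#' @return A `pipeline_config`.
#' @examples
#' cfg <- pipeline_profile("epipremnum")
#' cfg$overseg$r1
#' @export
pipeline_profile <- function(name = c("epipremnum", "monstera", "makoyana"),
                             z_min = 0.2, greenness = 0.1) {
  name <- match.arg(name)
  base_overseg <- overseg_params(r1 = 0.03, theta = 23, sigma1 = 0.025,
                                 r2 = 0.1)
  switch(name,
    epipremnum = pipeline_config(
      filter = filter_params(z_min = z_min, greenness = greenness,
                             radius = 0.015, min_neighbors = 85,
                             k = 40, std_mult = 1,
                             enabled = c("zaxis", "greenness", "radius",
                                         "statistical")),
      features = feature_params(K = 20, sigma1 = 0.025),
      overseg = base_overseg,
      grow = grow_params(sigma2 = 0.0055),
      profile = "epipremnum"),
    monstera = pipeline_config(
      filter = filter_params(z_min = z_min, k = 25, std_mult = 0.1,
                             enabled = c("zaxis", "statistical")),
      features = feature_params(K = 40, sigma1 = 0.025),
      overseg = base_overseg,
      grow = grow_params(sigma2 = 0.0025),
      profile = "monstera"),
    makoyana = pipeline_config(
      filter = filter_params(z_min = z_min, radius = 0.015,
                             min_neighbors = 50,
                             enabled = c("zaxis", "radius")),
      features = feature_params(K = 40, sigma1 = 0.025),
      overseg = base_overseg,
      grow = grow_params(sigma2 = 0.0055),
      profile = "makoyana")
  )
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML mirrors the four parameter objects field by field, so a config
#' round-trips losslessly.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    out <- unclass(x)
    if (is.null(out$adjacency_eps)) out$adjacency_eps <- "auto"
    out
  }
  yaml::write_yaml(list(profile = config$profile,
                        filter = unclass(config$filter),
                        features = unclass(config$features),
                        overseg = unclass(config$overseg),
                        grow = strip(config$grow)),
                   path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gr <- raw$grow
  if (identical(gr$adjacency_eps, "auto")) gr$adjacency_eps <- NULL
  pipeline_config(
    filter = do.call(filter_params, raw$filter),
    features = do.call(feature_params, raw$features),
    overseg = do.call(overseg_params, raw$overseg),
    grow = do.call(grow_params, gr),
    profile = raw$profile %||% "custom")
}

#' Run the full leaf-segmentation pipeline
#'
#' Executes preprocess -> feature estimation -> facet over-segmentation ->
#' facet region growing on a cloud (or a cloud file), optionally writing
#' every intermediate artifact. The run is deterministic given the
#' configuration's RNG seed.
#'
#' @param cloud a point cloud tibble, or a path readable by [read_cloud()].
#' @param config a [pipeline_config()].
#' @param out_prefix if non-`NULL`, write `<prefix>_filtered.ply`,
#'   `<prefix>_features.tsv`, `<prefix>_facets.labels`,
#'   `<prefix>_leaves.labels` and `<prefix>_report.json`.
#' @return An object of class `leaf_pipeline_run`: list with the input
#'   `cloud`, `filtered` cloud, `features`, `facets` (`facet_set`),
#'   `leaves` (`leaf_segmentation`) and a `report` list (per-stage point
#'   counts, facet/leaf counts, parameters).
#' @examples
#' canopy <- synthetic_canopy(n_leaves = 2, points_per_leaf = 150,
#'                            ground = FALSE, pot = FALSE, n_outliers = 0,
#'                            rng_seed = 1)
#' cfg <- pipeline_config(filter = filter_params(enabled = "zaxis",
#'                                               z_min = 0),
#'                        features = feature_params(K = 15))
#' run <- run_pipeline(canopy, cfg)
#' glance(run$leaves)
#' @export
run_pipeline <- function(cloud, config = pipeline_profile("epipremnum"),
                         out_prefix = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cloud)) cloud <- read_cloud(cloud)
  check_cloud(cloud)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  filtered <- stage("preprocess", preprocess_cloud(cloud, config$filter))
  feats <- stage("features", compute_features(filtered, config$features))
  facets <- stage("oversegment", oversegment(filtered, feats,
                                             config$overseg))
  leaves <- stage("growing", grow_leaves(facets, filtered, config$grow))
  report <- list(
    profile = config$profile,
    n_points_in = nrow(cloud),
    n_points_filtered = nrow(filtered),
    filter_log = filter_log(filtered),
    n_facets = nrow(facets$facets),
    kmeans_iterations = facets$kmeans_iterations,
    n_leaves = nrow(leaves$leaves),
    n_unassigned_points = sum(leaf_labels(leaves) < 0),
    parameters = list(filter = unclass(config$filter),
                      features = unclass(config$features),
                      overseg = unclass(config$overseg),
                      grow = unclass(config$grow))
  )
  run <- structure(list(cloud = cloud, filtered = filtered,
                        features = feats, facets = facets, leaves = leaves,
                        report = report),
                   class = "leaf_pipeline_run")
  if (!is.null(out_prefix)) {
    write_cloud(filtered, paste0(out_prefix, "_filtered.ply"))
    write_features(feats, paste0(out_prefix, "_features.tsv"))
    write_labels(facet_labels(facets), paste0(out_prefix, "_facets.labels"),
                 cloud = filtered)
    write_labels(leaf_labels(leaves), paste0(out_prefix, "_leaves.labels"),
                 cloud = filtered)
    rep_json <- report
    rep_json$filter_log <- as.data.frame(report$filter_log)
    rep_json$parameters$grow$adjacency_eps <-
      report$parameters$grow$adjacency_eps %||% "auto"
    jsonlite::write_json(rep_json, paste0(out_prefix, "_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  run
}

#' @export
print.leaf_pipeline_run <- function(x, ...) {
  cat("Leaf segmentation pipeline run (profile: ", x$report$profile, ")\n",
      "  points in:        ", x$report$n_points_in, "\n",
      "  after filtering:  ", x$report$n_points_filtered, "\n",
      "  facets:           ", x$report$n_facets, "\n",
      "  leaves:           ", x$report$n_leaves, "\n",
      "  unassigned points:", x$report$n_unassigned_points, "\n", sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object a `leaf_pipeline_run`.
#' @param ... unused.
#' @method glance leaf_pipeline_run
#' @export
glance.leaf_pipeline_run <- function(x, ...) {
  tibble(n_points_in = x$report$n_points_in,
         n_points_filtered = x$report$n_points_filtered,
         n_facets = x$report$n_facets,
         n_leaves = x$report$n_leaves,
         n_unassigned_points = x$report$n_unassigned_points)
}

#' @rdname run_pipeline
#' @method autoplot leaf_pipeline_run
#' @export
autoplot.leaf_pipeline_run <- function(object, ...) {
  plot_cloud(object$filtered, color = leaf_labels(object$leaves), ...)
}
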