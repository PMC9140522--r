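#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end run: the input mode (a
#' synthetic [scene_params] or a set of file paths, exactly one of the two),
#' MSPA edge width, connectivity thresholds, the AHP judgment matrix and
#' resistance scheme, corridor pruning and node merging parameters, and the
#' master seed.
#'
#' @param scene a [scene_params] object (synthetic mode), or `NULL`.
#' @param input_paths named list of file paths (`landcover`, `ndvi`, `dem`,
#'   `roads`, `mines`), or `NULL`.
#' @param edge_width MSPA structuring-element radius, cells.
#' @param d_threshold,p_threshold,k connectivity parameters: link threshold
#'   (m), dispersal probability at the threshold, number of sources.
#' @param judgment AHP [judgment_matrix].
#' @param scheme resistance scheme (see [default_resistance_scheme]).
#' @param weight_method AHP weight derivation method.
#' @param prune_overlap corridor redundancy threshold.
#' @param merge_radius node merge radius, cells.
#' @param include_crossings add corridor crossings as node candidates.
#' @param seed master seed; in synthetic mode it overrides the scene's seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_params(), input_paths = NULL,
                            edge_width = 1, d_threshold = 500,
                            p_threshold = 0.5, k = 10,
                            judgment = default_judgment_matrix(),
                            scheme = default_resistance_scheme(),
                            weight_method = "geometric_mean",
                            prune_overlap = 0.8, merge_radius = 3,
                            include_crossings = FALSE, seed = 1) {
  structure(list(scene = scene, input_paths = input_paths,
                 edge_width = edge_width, d_threshold = d_threshold,
                 p_threshold = p_threshold, k = k, judgment = judgment,
                 scheme = scheme, weight_method = weight_method,
                 prune_overlap = prune_overlap, merge_radius = merge_radius,
                 include_crossings = include_crossings,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every invariant and reports all violations at once rather than
#' failing on the first.
#'
#' @param config a [pipeline_config].
#' @return character vector of error messages (empty when the configuration
#'   is valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  say <- function(...) errs <<- c(errs, sprintf(...))
  if (!inherits(config, "pipeline_config")) {
    return("config must be created with pipeline_config()")
  }
  has_scene <- !is.null(config$scene)
  has_files <- !is.null(config$input_paths)
  if (has_scene == has_files) {
    say("exactly one input mode required: synthetic scene or file paths")
  }
  if (has_scene && !inherits(config$scene, "scene_params")) {
    say("`scene` must be a scene_params object")
  }
  if (has_files) {
    need <- c("landcover", "ndvi", "dem", "roads", "mines")
    miss <- setdiff(need, names(config$input_paths))
    if (length(miss)) say("missing input path(s): %s", paste(miss, collapse = ", "))
    for (nm in intersect(need, names(config$input_paths))) {
      if (!file.exists(config$input_paths[[nm]])) {
        say("input file for '%s' does not exist: %s", nm, config$input_paths[[nm]])
      }
    }
  }
  if (!is.numeric(config$edge_width) || config$edge_width < 1) {
    say("`edge_width` must be >= 1 cell")
  }
  if (!is.numeric(config$d_threshold) || config$d_threshold <= 0) {
    say("`d_threshold` must be a positive distance in metres")
  }
  if (!is.numeric(config$p_threshold) || config$p_threshold <= 0 ||
      config$p_threshold >= 1) {
    say("`p_threshold` must lie in (0, 1)")
  }
  if (!is.numeric(config$k) || config$k < 1) say("`k` must be >= 1")
  jm <- tryCatch({ judgment_matrix(unclass(config$judgment)); NULL },
                 error = function(e) conditionMessage(e))
  if (!is.null(jm)) say("judgment matrix invalid: %s", jm)
  w <- config$scheme$weights
  if (is.null(w)) {
    say("resistance scheme must carry a `weights` vector")
  } else if (abs(sum(w) - 1) > 1e-6) {
    say("factor weights must sum to 1 (got %.6f)", sum(w))
  }
  for (nm in setdiff(names(config$scheme), "weights")) {
    sc <- config$scheme[[nm]]
    if (identical(sc$type, "bands")) {
      if (any(sc$value < 1 | sc$value > 500)) {
        say("factor '%s': resistance values must lie in [1, 500]", nm)
      }
      if (any(utils::head(sc$hi, -1) != sc$lo[-1])) {
        say("factor '%s': bands must tile the domain without gaps", nm)
      }
    } else if (identical(sc$type, "categorical")) {
      if (any(sc$map < 1 | sc$map > 500)) {
        say("factor '%s': resistance values must lie in [1, 500]", nm)
      }
    }
  }
  if (!is.numeric(config$prune_overlap) || config$prune_overlap < 0) {
    say("`prune_overlap` must be >= 0")
  }
  if (!is.numeric(config$merge_radius) || config$merge_radius < 0) {
    say("`merge_radius` must be >= 0")
  }
  errs
}

round_num <- function(x, digits = 6) {
  if (is.numeric(x)) round(x, digits) else x
}

#' Run the full ecological-security-pattern pipeline
#'
#' Executes generation (or loading) of the layer bundle, NDVI/slope/distance
#' derivations, MSPA segmentation, patch connectivity and source selection,
#' AHP-weighted resistance construction, corridor extraction, ridgeline and
#' node identification; writes every intermediate artifact plus a
#' machine-readable JSON summary to `out_dir`. Identical configuration and
#' seed produce a byte-identical summary.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress per-stage log lines.
#' @return invisibly, an object of class `esp_run` with every intermediate
#'   result and the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("esp_run_"),
                         quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  # ---- inputs ----
  if (!is.null(config$scene)) {
    sp <- config$scene
    sp$seed <- config$seed
    scene <- generate_scene(sp)
    log_stage("generate", "synthetic scene %dx%d, seed %d",
              sp$shape[1], sp$shape[2], sp$seed)
  } else {
    p <- config$input_paths
    scene <- list(landcover = read_raster(p$landcover),
                  ndvi = read_raster(p$ndvi), dem = read_raster(p$dem),
                  roads = read_raster(p$roads), mines = read_raster(p$mines))
    scene$slope <- slope_from_dem(scene$dem)
    check_alignment(scene$landcover, scene$ndvi, scene$dem, scene$roads,
                    scene$mines)
    log_stage("load", "read %d layers from files", 5)
  }
  cs <- scene$landcover$cell_size
  nr <- nrow(scene$landcover$values); nc <- ncol(scene$landcover$values)

  # distance factors; a scene without roads (or mines) has no feature to
  # measure from, so the whole surface falls in the farthest (lowest
  # resistance) band
  dist_layer <- function(r) {
    if (any(r$values != 0, na.rm = TRUE)) distance_to_features(r)
    else grid_raster(matrix(1e9, nr, nc), cs, r$origin, r$crs_tag, r$nodata)
  }
  dist_road <- dist_layer(scene$roads)
  dist_mine <- dist_layer(scene$mines)

  # ---- MSPA ----
  fg <- make_foreground(scene$landcover)
  seg <- mspa_segment(fg, config$edge_width)
  log_stage("mspa", "foreground %d cells; core %d cells",
            sum(fg$values != 0), sum(seg$classes$values == 1))

  # ---- connectivity and sources ----
  patches <- extract_patches(seg)
  if (!length(patches)) {
    stop("no ecological sources: MSPA found no core patches ",
         "(is there any vegetation or water in the scene?)")
  }
  AL <- nr * nc * cs^2 / 1e4
  pg <- patch_graph(patches, AL, cs, config$d_threshold, config$p_threshold)
  ranking <- connectivity_ranking(pg)
  sources <- select_sources(patches, delta_importance(pg, "PC"), config$k)
  log_stage("connect", "%d patches, IIC %.4g, PC %.4g, %d sources",
            length(patches), iic(pg), pc(pg), length(sources))

  # ---- resistance ----
  weights <- ahp_weights(config$judgment, config$weight_method)
  cons <- consistency_ratio(config$judgment, config$weight_method)
  factors <- list(
    land_use = reclassify_factor(scene$landcover, config$scheme$land_use),
    ndvi = reclassify_factor(scene$ndvi, config$scheme$ndvi),
    slope = reclassify_factor(scene$slope, config$scheme$slope),
    dem = reclassify_factor(scene$dem, config$scheme$dem),
    dist_road = reclassify_factor(dist_road, config$scheme$dist_road),
    dist_mine = reclassify_factor(dist_mine, config$scheme$dist_mine))
  resistance <- weighted_overlay(factors, weights)
  log_stage("resist", "CR %.4f; surface range [%.4f, %.4f]", cons$CR,
            min(resistance$values, na.rm = TRUE),
            max(resistance$values, na.rm = TRUE))

  # ---- corridors, ridgelines, nodes ----
  corridors <- build_corridors(sources, resistance, config$prune_overlap)
  ridge <- extract_ridgelines(scene$dem)
  nodes <- identify_nodes(corridors, ridge, config$merge_radius,
                          config$include_crossings)
  log_stage("corridors", "%d corridors, %.3f km; %d nodes",
            corridors$n_corridors, corridors$total_length_km, nrow(nodes))

  # ---- artifacts ----
  wr <- function(r, name) write_raster(r, file.path(out_dir, paste0(name, ".asc")))
  wr(scene$landcover, "landcover"); wr(scene$ndvi, "ndvi")
  wr(scene$dem, "dem"); wr(scene$slope, "slope")
  wr(fg, "foreground"); wr(seg$classes, "mspa_classes")
  wr(resistance, "resistance")
  wr(grid_raster(ridge$values, cs, ridge$origin, ridge$crs_tag), "ridgelines")
  for (i in seq_along(corridors$accumulated)) {
    wr(corridors$accumulated[[i]], sprintf("cost_source_%02d", i))
  }
  utils::write.csv(seg$statistics, file.path(out_dir, "mspa_statistics.csv"),
                   row.names = FALSE)
  utils::write.csv(ranking, file.path(out_dir, "connectivity_ranking.csv"),
                   row.names = FALSE)
  # Conefor-style node/connection files
  writeLines(sprintf("%d %.6f", vapply(patches, `[[`, numeric(1), "id"),
                     vapply(patches, `[[`, numeric(1), "area_ha")),
             file.path(out_dir, "conefor_nodes.txt"))
  lp <- which(upper.tri(pg$dist), arr.ind = TRUE)
  writeLines(sprintf("%d %d %.6f", lp[, 1], lp[, 2], pg$dist[lp]),
             file.path(out_dir, "conefor_connections.txt"))
  # GeoJSON exports
  cell_line <- function(cells) {
    xy <- cell_center_xy(scene$landcover, cells[, 1], cells[, 2])
    lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))
  }
  ret <- which(corridors$corridors$retained)
  write_geojson(lapply(ret, function(m) {
    list(type = "LineString", coordinates = cell_line(corridors$paths[[m]]),
         properties = list(from = corridors$corridors$from[m],
                           to = corridors$corridors$to[m],
                           cost = round_num(corridors$corridors$cost[m]),
                           length_km = round_num(corridors$corridors$length_km[m])))
  }), file.path(out_dir, "corridors.geojson"))
  write_geojson(lapply(seq_len(nrow(nodes)), function(i) {
    list(type = "Point", coordinates = c(nodes$x[i], nodes$y[i]),
         properties = list(node = nodes$node[i],
                           corridors = nodes$corridors[i]))
  }), file.path(out_dir, "nodes.geojson"))
  write_geojson(lapply(sources, function(p) {
    half <- cs / 2
    xy <- cell_center_xy(scene$landcover, p$cells[, 1], p$cells[, 2])
    sq <- lapply(seq_len(nrow(xy)), function(i) {
      x <- xy[i, 1]; y <- xy[i, 2]
      list(list(c(x - half, y - half), c(x + half, y - half),
                c(x + half, y + half), c(x - half, y + half),
                c(x - half, y - half)))
    })
    list(type = "MultiPolygon", coordinates = sq,
         properties = list(patch = p$id, area_ha = p$area_ha))
  }), file.path(out_dir, "sources.geojson"))

  # ---- summary ----
  stats <- seg$statistics
  summary <- list(
    seed = config$seed,
    shape = c(nr, nc), cell_size = cs, landscape_area_ha = round_num(AL),
    mspa = stats::setNames(as.list(round_num(stats$area_ha)), stats$class),
    n_patches = length(patches),
    iic = round_num(iic(pg), 8), pc = round_num(pc(pg), 8),
    n_sources = length(sources),
    source_area_ha = round_num(sum(vapply(sources, `[[`, numeric(1), "area_ha"))),
    weights = as.list(round_num(weights, 6)),
    lambda_max = round_num(cons$lambda_max, 6), cr = round_num(cons$CR, 6),
    resistance_min = round_num(min(resistance$values, na.rm = TRUE)),
    resistance_max = round_num(max(resistance$values, na.rm = TRUE)),
    n_corridors = corridors$n_corridors,
    n_raw_corridors = nrow(corridors$corridors),
    total_corridor_length_km = round_num(corridors$total_length_km),
    n_nodes = nrow(nodes))
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(out_dir, "summary.json"))

  out <- structure(list(config = config, scene = scene, foreground = fg,
                        segmentation = seg, patches = patches, graph = pg,
                        ranking = ranking, sources = sources,
                        weights = weights, consistency = cons,
                        resistance = resistance, corridors = corridors,
                        ridge = ridge, nodes = nodes, summary = summary,
                        out_dir = out_dir),
                   class = "esp_run")
  invisible(out)
}

#' @export
print.esp_run <- function(x, ...) {
  s <- x$summary
  cat("<esp_run>\n")
  cat(sprintf("  scene: %d x %d cells (%g m), seed %d\n",
              s$shape[1], s$shape[2], s$cell_size, s$seed))
  cat(sprintf("  patches: %d, sources: %d (%.2f ha)\n", s$n_patches,
              s$n_sources, s$source_area_ha))
  cat(sprintf("  AHP: lambda_max %.4f, CR %.4f\n", s$lambda_max, s$cr))
  cat(sprintf("  resistance: [%.4f, %.4f]\n", s$resistance_min, s$resistance_max))
  cat(sprintf("  corridors: %d (%.3f km), nodes: %d\n", s$n_corridors,
              s$total_corridor_length_km, s$n_nodes))
  cat(sprintf("  artifacts: %s\n", x$out_dir))
  invisible(x)
}
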