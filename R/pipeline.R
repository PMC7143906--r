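# End-to-end pipeline: grid -> merge -> layers -> score -> classify ->
# allocate, with tabular and GeoJSON reports.

#' Configure a pressure-assessment pipeline
#'
#' All defaults reproduce the original study setup: 10 km cells, the
#' twelve-layer default registry, merge threshold at half a cell, four
#' pressure classes with upper edges 10/20/30 and 1-4 wells per block.
#'
#' @param cell_size grid cell side in metres.
#' @param min_area_fraction merge threshold as a fraction of the nominal
#'   cell area.
#' @param scheme a [class_scheme()].
#' @param registry `"default"`, a data frame, or a CSV path (see
#'   [load_registry()]).
#' @param simulate if `TRUE` (default) the study area and layers are
#'   simulated; otherwise `area_file` and `point_files` are read.
#' @param shape,width,height,process,n_parents,cluster_radius,layer_counts
#'   simulation settings passed to [simulate_area()] / [simulate_layers()].
#' @param area_file path to a GeoJSON or WKT study-area file (real-data
#'   mode).
#' @param area_format `"geojson"` or `"wkt"`.
#' @param crs CRS identifier of all coordinates (projected metric).
#' @param point_files named character vector of per-layer point file paths
#'   (names are layer names; CSV or GeoJSON).
#' @param well_mode well-siting mode for [place_wells()] (default
#'   `"none"`).
#' @param seed integer root seed for all randomness.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_size = 10000, min_area_fraction = 0.5,
                            scheme = class_scheme(), registry = "default",
                            simulate = TRUE, shape = "peninsula",
                            width = 60000, height = 55000,
                            process = "uniform", n_parents = 8L,
                            cluster_radius = 3000,
                            layer_counts = default_layer_counts(),
                            area_file = NULL, area_format = c("geojson", "wkt"),
                            crs = "EPSG:3035", point_files = NULL,
                            well_mode = "none", seed = 1L) {
  structure(list(
    cell_size = cell_size, min_area_fraction = min_area_fraction,
    scheme = scheme, registry = registry, simulate = simulate, shape = shape,
    width = width, height = height, process = process, n_parents = n_parents,
    cluster_radius = cluster_radius, layer_counts = layer_counts,
    area_file = area_file, area_format = match.arg(area_format), crs = crs,
    point_files = point_files, well_mode = well_mode, seed = as.integer(seed)
  ), class = "pipeline_config")
}

run_stage <- function(name, expr, quiet) {
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "gwp_stage_error", parent = e)
  })
  if (!quiet) inform(sprintf("[%s] done", name))
  res
}

#' Run the full pressure-assessment pipeline
#'
#' Executes grid construction, small-block merging, layer loading or
#' simulation, point assignment, block scoring, classification and well
#' allocation, and optionally writes the report bundle to disk:
#' `layer_summary.csv` (layer, weight, count, total score),
#' `block_scores.csv`, `allocations.csv`, `class_summary.csv`,
#' `blocks.geojson` (block geometry with score/class/wells properties) and
#' `report_full.json` (full-precision machine-readable sidecar). CSV report
#' columns are rounded to 1 decimal, the study's printed precision. If any
#' stage fails, partial outputs are removed.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for the report bundle (created if needed);
#'   `NULL` writes nothing.
#' @param quiet suppress per-stage progress messages.
#' @return an object of class `pressure_report`: a list with `config`,
#'   `area`, `blocks`, `registry`, `points` (assigned), `layer_summary`,
#'   `scores`, `allocation`, `class_summary` and `files` (paths written).
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 7), quiet = TRUE)
#' glance(rep)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))

  registry <- run_stage("registry", load_registry(config$registry), quiet)

  area <- run_stage("area", {
    if (config$simulate) {
      simulate_area(config$shape, width = config$width, height = config$height,
                    crs = config$crs)
    } else {
      if (is.null(config$area_file)) {
        abort("simulate = FALSE but no `area_file` given", class = "gwp_argument_error")
      }
      if (config$area_format == "wkt") read_area_wkt(config$area_file, crs = config$crs)
      else read_area_geojson(config$area_file, crs = config$crs)
    }
  }, quiet)

  blocks <- run_stage("grid", {
    g <- make_grid(area, cell_size = config$cell_size)
    merge_small_blocks(g, min_area_fraction = config$min_area_fraction)
  }, quiet)

  points <- run_stage("layers", {
    if (config$simulate) {
      simulate_layers(area, counts = config$layer_counts,
                      process = config$process, n_parents = config$n_parents,
                      cluster_radius = config$cluster_radius,
                      seed = config$seed, registry = registry)
    } else if (!is.null(config$point_files)) {
      dplyr::bind_rows(lapply(names(config$point_files), function(nm) {
        load_points(config$point_files[[nm]], nm)
      }))
    } else {
      tibble(layer = character(0), x = numeric(0), y = numeric(0))
    }
  }, quiet)

  assigned <- run_stage("assign", assign_points(points, blocks, quiet = quiet), quiet)
  unassigned <- attr(assigned, "unassigned") %||% 0L
  if (unassigned > 0 && !quiet) {
    warn(sprintf("%d point(s) fall outside the study area and are excluded from scores",
                 unassigned))
  }

  lsum <- run_stage("layer_summary", layer_summary(points, registry), quiet)
  scores <- run_stage("score", score_blocks(assigned, blocks, registry), quiet)
  allocation <- run_stage("classify", {
    alloc <- allocate_wells(scores, config$scheme)
    place_wells(alloc, blocks, mode = config$well_mode, points = assigned,
                registry = registry, seed = config$seed)
  }, quiet)
  csum <- run_stage("summary", allocation_summary(allocation, config$scheme), quiet)

  report <- structure(list(
    config = config, area = area, blocks = blocks, registry = registry,
    points = assigned, layer_summary = lsum, scores = scores,
    allocation = allocation, class_summary = csum, files = character(0)
  ), class = "pressure_report")

  if (!is.null(output_dir)) {
    report$files <- run_stage("write", write_report(report, output_dir), quiet)
  }
  report
}

write_report <- function(report, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- file.path(output_dir, c("layer_summary.csv", "block_scores.csv",
                                   "allocations.csv", "class_summary.csv",
                                   "blocks.geojson", "report_full.json"))
  names(files) <- c("layer_summary", "block_scores", "allocations",
                    "class_summary", "blocks", "sidecar")
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)

  lsum <- dplyr::mutate(report$layer_summary, total_score = round(.data$total_score, 1))
  readr::write_csv(lsum, files["layer_summary"])

  sc <- as_tibble(report$scores)
  sc$raw_total <- NULL
  readr::write_csv(sc, files["block_scores"])

  alloc <- as_tibble(report$allocation)
  alloc$wells <- NULL
  readr::write_csv(alloc, files["allocations"])

  readr::write_csv(as_tibble(report$class_summary), files["class_summary"])

  props <- dplyr::left_join(
    as_tibble(report$scores)[, c("block_id", "total")],
    as_tibble(report$allocation)[, c("block_id", "pressure_class", "n_wells")],
    by = "block_id")
  write_blocks_geojson(report$blocks, files["blocks"], properties = props)

  sidecar <- list(
    layer_summary = report$layer_summary,
    block_scores = as_tibble(report$scores)[, c("block_id", "raw_total", "total")],
    class_summary = as_tibble(report$class_summary),
    totals = list(blocks = nrow(report$blocks),
                  wells = sum(report$allocation$n_wells),
                  points = nrow(report$points),
                  unassigned = attr(report$points, "unassigned") %||% 0L)
  )
  jsonlite::write_json(sidecar, files["sidecar"], digits = NA, auto_unbox = TRUE)
  ok <- TRUE
  files
}

#' @export
print.pressure_report <- function(x, ...) {
  g <- glance(x)
  cat("<pressure_report>\n")
  cat(sprintf("  blocks: %d (cell %.0f m), points: %d (%d unassigned)\n",
              g$n_blocks, x$config$cell_size, g$n_points, g$n_unassigned))
  cat(sprintf("  scores: %.1f - %.1f, classes: %s, wells: %d\n",
              g$score_min, g$score_max,
              paste(x$class_summary$n_blocks, collapse = "/"), g$total_wells))
  invisible(x)
}

#' Tidy per-block results of a pipeline run
#'
#' @param x a `pressure_report` from [run_pipeline()].
#' @param ... unused.
#' @return tibble with one row per block: `block_id`, `actual_area`,
#'   `merged_n` (number of absorbed blocks), layer counts, `total`,
#'   `pressure_class`, `n_wells`.
#' @export
tidy.pressure_report <- function(x, ...) {
  base <- tibble(block_id = x$blocks$block_id,
                 actual_area = x$blocks$actual_area,
                 merged_n = vapply(x$blocks$merged_from,
                                   function(m) length(setdiff(m, UNMERGEABLE)),
                                   integer(1)))
  base |>
    dplyr::left_join(as_tibble(x$scores), by = "block_id") |>
    dplyr::left_join(as_tibble(x$allocation)[, c("block_id", "pressure_class", "n_wells")],
                     by = "block_id")
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.pressure_report
#' @return one-row tibble: `n_blocks`, `n_points`, `n_unassigned`,
#'   `score_min`, `score_max`, `total_wells`.
#' @export
glance.pressure_report <- function(x, ...) {
  tibble(
    n_blocks = nrow(x$blocks),
    n_points = nrow(x$points),
    n_unassigned = attr(x$points, "unassigned") %||% 0L,
    score_min = min(x$scores$total),
    score_max = max(x$scores$total),
    total_wells = sum(x$allocation$n_wells)
  )
}
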