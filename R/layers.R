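# The registry of weighted pressure layers and their point data.
#
# A layer is one type of potential contamination source (e.g. landfills,
# livestock farms, sinkholes), represented as georeferenced points with an
# attributed weight in [0, 1] reflecting its potential impact on
# groundwater. The default registry carries the twelve layers of the
# original assessment; eleven are anthropic pressures, sinkholes are the
# single natural one.

DEFAULT_LAYERS <- tibble::tribble(
  ~layer,                                                        ~weight, ~kind,
  "Urban Waste Water discharges",                                  0.3, "anthropic",
  "Industrial Plants (Integrated Environmental Authorization)",    0.8, "anthropic",
  "Potentially Contaminated Sites",                                1.0, "anthropic",
  "Companies authorized for Waste storage and management",         0.8, "anthropic",
  "Companies authorized to emit certain atmospheric pollutants",   0.5, "anthropic",
  "PCB Waste treatment and management Plants",                     1.0, "anthropic",
  "Livestock farm",                                                0.1, "anthropic",
  "Active quarries",                                               0.2, "anthropic",
  "Urban solid waste landfill",                                    1.0, "anthropic",
  "Major-accident hazards industrial activities",                  0.2, "anthropic",
  "Disused and abandoned quarries",                                0.6, "anthropic",
  "Sinkholes",                                                     0.8, "natural"
)

#' The default pressure-layer registry
#'
#' Twelve layers of anthropic/environmental pressure on groundwater with
#' their attributed weights (expert-judgment scores in `[0, 1]`): urban
#' waste-water discharges (0.3), IPPC industrial plants (0.8), potentially
#' contaminated sites (1), waste storage and management companies (0.8),
#' authorized atmospheric emitters (0.5), PCB treatment plants (1),
#' livestock farms (0.1), active quarries (0.2), urban solid-waste landfills
#' (1), major-accident-hazard industries (0.2), disused quarries (0.6) and
#' sinkholes (0.8, the only natural pressure).
#'
#' @return tibble of class `gw_registry` with columns `layer`, `weight`,
#'   `kind`.
#' @export
default_registry <- function() {
  reg <- DEFAULT_LAYERS
  class(reg) <- c("gw_registry", class(reg))
  reg
}

#' Load a pressure-layer registry
#'
#' @param source `"default"` for the built-in twelve-layer registry, a data
#'   frame with columns `layer` (or `name`) and `weight` and optionally
#'   `kind`, or the path of a CSV/TSV file with those columns.
#' @return tibble of class `gw_registry` with columns `layer`, `weight`,
#'   `kind`.
#' @export
load_registry <- function(source = "default") {
  if (is.character(source) && length(source) == 1 && source == "default") {
    return(default_registry())
  }
  df <- if (is.data.frame(source)) {
    as_tibble(source)
  } else if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      abort(paste0("registry file not found: ", source), class = "gwp_io_error")
    }
    delim <- if (grepl("\\.tsv$", source, ignore.case = TRUE)) "\t" else ","
    readr::read_delim(source, delim = delim, show_col_types = FALSE)
  } else {
    abort("`source` must be \"default\", a data frame, or a file path",
          class = "gwp_argument_error")
  }
  if ("name" %in% names(df) && !"layer" %in% names(df)) {
    df <- dplyr::rename(df, layer = "name")
  }
  if (!all(c("layer", "weight") %in% names(df))) {
    abort("registry needs `layer` (or `name`) and `weight` columns",
          class = "gwp_validation_error")
  }
  if (!"kind" %in% names(df)) df$kind <- "anthropic"
  df <- dplyr::select(df, "layer", "weight", "kind")
  validate_registry(df)
  class(df) <- c("gw_registry", class(tibble()))
  df
}

validate_registry <- function(df) {
  if (!is.numeric(df$weight) || anyNA(df$weight) ||
      any(df$weight < 0) || any(df$weight > 1)) {
    bad <- df$layer[is.na(df$weight) | df$weight < 0 | df$weight > 1]
    abort(paste0("layer weight outside [0, 1]: ",
                 paste(bad, collapse = ", ")), class = "gwp_validation_error")
  }
  key <- norm_layer_name(df$layer)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate layer name: ",
                 paste(unique(df$layer[duplicated(key)]), collapse = ", ")),
          class = "gwp_validation_error")
  }
  invisible(df)
}

# case-insensitive, whitespace-normalised matching key for layer names
norm_layer_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Match layer names against a registry
#'
#' Names match case-insensitively after whitespace normalisation; a name
#' absent from the registry is an error, never silently created.
#' @keywords internal
#' @noRd
match_layers <- function(names, registry) {
  idx <- match(norm_layer_name(names), norm_layer_name(registry$layer))
  if (anyNA(idx)) {
    abort(paste0("unknown layer name(s): ",
                 paste(unique(names[is.na(idx)]), collapse = ", ")),
          class = "gwp_validation_error")
  }
  idx
}

#' Load pressure points for one layer
#'
#' Reads point locations from a CSV file with numeric `x`, `y` columns or
#' from a GeoJSON file of Point features. Exact duplicate coordinates are
#' retained: two facilities can share a location.
#'
#' @param source path to a CSV or GeoJSON point file.
#' @param layer_name canonical layer name to attach to the points.
#' @return tibble with columns `layer`, `x`, `y`, one row per point.
#' @export
load_points <- function(source, layer_name) {
  if (!is.character(source) || length(source) != 1 || !file.exists(source)) {
    abort(paste0("point file not found: ", source), class = "gwp_io_error")
  }
  if (grepl("\\.(geojson|json)$", source, ignore.case = TRUE)) {
    g <- parse_geojson(source)
    pts <- geojson_points(g)
  } else {
    df <- tryCatch(
      readr::read_csv(source, show_col_types = FALSE, progress = FALSE),
      error = function(e) abort(paste0("cannot read point CSV: ",
                                       conditionMessage(e)), class = "gwp_io_error")
    )
    if (!all(c("x", "y") %in% names(df))) {
      abort("point CSV needs `x` and `y` columns", class = "gwp_validation_error")
    }
    if (!is.numeric(df$x) || !is.numeric(df$y) || anyNA(df$x) || anyNA(df$y)) {
      abort("non-numeric coordinates in point CSV", class = "gwp_validation_error")
    }
    pts <- tibble(x = as.numeric(df$x), y = as.numeric(df$y))
  }
  inform(sprintf("layer '%s': %d point(s) loaded", layer_name, nrow(pts)))
  tibble(layer = rep(layer_name, nrow(pts)), x = pts$x, y = pts$y)
}

geojson_points <- function(g) {
  type <- g$type %||% abort("GeoJSON object has no 'type'", class = "gwp_validation_error")
  feats <- switch(type,
    FeatureCollection = lapply(g$features, `[[`, "geometry"),
    Feature = list(g$geometry),
    Point = list(g),
    abort(sprintf("unsupported GeoJSON type '%s' for points", type),
          class = "gwp_validation_error")
  )
  xy <- matrix(NA_real_, nrow = length(feats), ncol = 2)
  for (i in seq_along(feats)) {
    geom <- feats[[i]]
    if (is.null(geom$type) || geom$type != "Point") {
      abort(sprintf("feature %d is not a Point (got '%s')", i,
                    geom$type %||% "NULL"), class = "gwp_validation_error")
    }
    xy[i, ] <- c(as.numeric(geom$coordinates[[1]]), as.numeric(geom$coordinates[[2]]))
  }
  if (anyNA(xy)) {
    abort("non-numeric coordinates in GeoJSON points", class = "gwp_validation_error")
  }
  tibble(x = xy[, 1], y = xy[, 2])
}

#' Per-layer point counts and total scores
#'
#' Summarises a point table against a registry: for each layer the number of
#' identified pressures `n` and its total score `n * weight`. With the
#' original registry and point counts this reproduces the published
#' per-layer summary table.
#'
#' @param points tibble with columns `layer`, `x`, `y` (or just `layer`);
#'   every layer name must exist in the registry.
#' @param registry a `gw_registry` (default: [default_registry()]).
#' @return tibble with columns `layer`, `weight`, `kind`, `n`,
#'   `total_score` (= `n * weight`, full precision; round to 1 decimal for
#'   display), one row per registry layer in registry order.
#' @examples
#' pts <- data.frame(layer = rep("Sinkholes", 3), x = 1:3, y = 1:3)
#' layer_summary(pts)
#' @export
layer_summary <- function(points, registry = default_registry()) {
  registry <- load_registry(registry)
  if (nrow(points) > 0) match_layers(points$layer, registry)
  counts <- dplyr::count(as_tibble(points), layer_key = norm_layer_name(.data$layer))
  out <- registry |>
    dplyr::mutate(layer_key = norm_layer_name(.data$layer)) |>
    dplyr::left_join(counts, by = "layer_key") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  total_score = .data$n * .data$weight) |>
    dplyr::select("layer", "weight", "kind", "n", "total_score")
  as_tibble(out)
}

#' Total score of one layer
#'
#' `n * weight`: the number of identified pressure points times the layer's
#' attributed weight.
#'
#' @param n non-negative point count (vectorised).
#' @param weight layer weight in `[0, 1]` (vectorised).
#' @return numeric total score(s).
#' @export
layer_total_score <- function(n, weight) {
  if (any(n < 0)) abort("point count must be non-negative", class = "gwp_validation_error")
  if (any(weight < 0 | weight > 1)) {
    abort("weight must be in [0, 1]", class = "gwp_validation_error")
  }
  n * weight
}
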