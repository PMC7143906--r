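#' Define a study area
#'
#' A study area is the spatial universe of the analysis: a polygon (possibly
#' with holes, possibly multi-part) in a projected coordinate reference
#' system with metre units, plus the identifier of that CRS. Cell sizes are
#' given in metres, so geographic (degree) coordinate systems are rejected
#' rather than silently reprojected.
#'
#' @param boundary either a data frame with numeric columns `x`, `y` and an
#'   optional `ring` column (one row per vertex, rings in order: exterior
#'   rings counter-clockwise, holes clockwise — orientation is normalised
#'   internally), or a list of rings, each `list(x =, y =)`.
#' @param crs character CRS identifier (e.g. `"EPSG:3035"`). Must refer to a
#'   projected metric CRS; well-known geographic identifiers (EPSG:4326 and
#'   friends) raise an error.
#' @return an object of class `study_area`: a list with elements `rings`
#'   (normalised polyset), `crs`, and `area` (m^2).
#' @examples
#' sq <- study_area(data.frame(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000)))
#' sq$area
#' @export
study_area <- function(boundary, crs = "EPSG:3035") {
  rings <- as_rings(boundary)
  check_projected_crs(crs)
  validate_rings(rings)
  rings <- normalise_rings(rings)
  a <- polyset_area(rings)
  if (a <= 0) {
    abort("study area polygon has non-positive area", class = "gwp_validation_error")
  }
  structure(list(rings = rings, crs = crs, area = a), class = "study_area")
}

as_rings <- function(boundary) {
  if (inherits(boundary, "study_area")) return(boundary$rings)
  if (is.data.frame(boundary)) {
    if (!all(c("x", "y") %in% names(boundary))) {
      abort("boundary data frame needs `x` and `y` columns",
            class = "gwp_argument_error")
    }
    ring_id <- if ("ring" %in% names(boundary)) boundary$ring else rep(1L, nrow(boundary))
    return(lapply(split(boundary, ring_id), function(d) list(x = d$x, y = d$y)))
  }
  if (is.list(boundary) && length(boundary) > 0 &&
      all(vapply(boundary, function(r) is.list(r) && all(c("x", "y") %in% names(r)),
                 logical(1)))) {
    return(boundary)
  }
  abort("boundary must be a data frame with x/y columns or a list of rings",
        class = "gwp_argument_error")
}

# Known geographic (degree-unit) CRS identifiers; these make a metre cell
# size meaningless, so they are rejected up front.
GEOGRAPHIC_CRS <- c("EPSG:4326", "EPSG:4258", "EPSG:4269", "EPSG:4267",
                    "WGS84", "WGS 84", "CRS84", "OGC:CRS84")

check_projected_crs <- function(crs) {
  if (!is.character(crs) || length(crs) != 1 || is.na(crs) || !nzchar(crs)) {
    abort("`crs` must be a single non-empty character string",
          class = "gwp_argument_error")
  }
  if (toupper(gsub("\\s+", " ", trimws(crs))) %in% toupper(GEOGRAPHIC_CRS)) {
    abort(
      paste0("geographic CRS '", crs, "' has degree units; ",
             "supply coordinates in a projected metric CRS"),
      class = "gwp_validation_error"
    )
  }
  invisible(crs)
}

validate_rings <- function(rings) {
  for (i in seq_along(rings)) {
    r <- rings[[i]]
    if (length(r$x) != length(r$y)) {
      abort(sprintf("ring %d: x and y lengths differ", i),
            class = "gwp_validation_error")
    }
    if (anyNA(r$x) || anyNA(r$y) || any(!is.finite(r$x)) || any(!is.finite(r$y))) {
      abort(sprintf("ring %d: non-finite coordinates", i),
            class = "gwp_validation_error")
    }
    if (length(r$x) < 3) {
      abort(sprintf("ring %d: fewer than 3 vertices", i),
            class = "gwp_validation_error")
    }
    # A simple (non-self-intersecting) ring survives Clipper simplification
    # as a single ring of identical area.
    simp <- polyclip::polysimplify(list(r), filltype = "evenodd")
    a0 <- abs(ring_signed_area(r))
    a1 <- abs(polyset_area(simp))
    if (length(simp) != 1L || abs(a1 - a0) > 1e-6 * max(a0, 1)) {
      abort(sprintf("ring %d is self-intersecting or degenerate", i),
            class = "gwp_validation_error")
    }
  }
  invisible(rings)
}

# Normalise ring orientation (exterior CCW, holes CW) without touching the
# coordinates: a ring nested in an odd number of other rings is a hole under
# the even-odd rule, and is flipped to clockwise if needed.
normalise_rings <- function(rings) {
  lapply(seq_along(rings), function(i) {
    v <- rings[[i]]
    depth <- sum(vapply(seq_along(rings), function(j) {
      j != i && points_in_polyset(v$x[1], v$y[1], rings[j])
    }, logical(1)))
    a <- ring_signed_area(v)
    is_hole <- depth %% 2 == 1
    if ((is_hole && a > 0) || (!is_hole && a < 0)) {
      v <- list(x = rev(v$x), y = rev(v$y))
    }
    v
  })
}

#' @export
print.study_area <- function(x, ...) {
  bb <- polyset_bbox(x$rings)
  cat(sprintf(
    "<study_area> %d ring(s), area %.1f km^2, bbox [%.0f, %.0f] x [%.0f, %.0f], crs %s\n",
    length(x$rings), x$area / 1e6, bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"], x$crs
  ))
  invisible(x)
}

#' Read a study area from GeoJSON
#'
#' Accepts a Polygon or MultiPolygon geometry, a Feature wrapping one, or a
#' FeatureCollection whose first feature wraps one.
#'
#' @param source path to a GeoJSON file, or a GeoJSON string.
#' @param crs CRS identifier of the coordinates (GeoJSON itself does not
#'   carry one); must be projected metric.
#' @return a [study_area()].
#' @export
read_area_geojson <- function(source, crs = "EPSG:3035") {
  g <- parse_geojson(source)
  rings <- geojson_polygon_rings(g)
  study_area(rings, crs = crs)
}

#' Read a study area from WKT
#'
#' Accepts `POLYGON ((...))` or `MULTIPOLYGON (((...)))` text, from a string
#' or a file.
#'
#' @inheritParams read_area_geojson
#' @return a [study_area()].
#' @export
read_area_wkt <- function(source, crs = "EPSG:3035") {
  txt <- if (file.exists(source)) paste(readLines(source, warn = FALSE), collapse = " ") else source
  rings <- wkt_polygon_rings(txt)
  study_area(rings, crs = crs)
}

parse_geojson <- function(source) {
  txt <- if (length(source) == 1 && !grepl("\\{", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    source
  }
  tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) abort(paste0("cannot parse GeoJSON: ", conditionMessage(e)),
                              class = "gwp_io_error")
  )
}

geojson_polygon_rings <- function(g) {
  type <- g$type %||% abort("GeoJSON object has no 'type'", class = "gwp_validation_error")
  if (type == "FeatureCollection") {
    if (length(g$features) == 0) {
      abort("FeatureCollection has no features", class = "gwp_validation_error")
    }
    return(geojson_polygon_rings(g$features[[1]]$geometry))
  }
  if (type == "Feature") return(geojson_polygon_rings(g$geometry))
  coords_to_ring <- function(cc) {
    x <- vapply(cc, function(p) as.numeric(p[[1]]), numeric(1))
    y <- vapply(cc, function(p) as.numeric(p[[2]]), numeric(1))
    n <- length(x)
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) { # drop GeoJSON closing vertex
      x <- x[-n]; y <- y[-n]
    }
    list(x = x, y = y)
  }
  if (type == "Polygon") {
    return(lapply(g$coordinates, coords_to_ring))
  }
  if (type == "MultiPolygon") {
    return(unlist(lapply(g$coordinates, function(poly) lapply(poly, coords_to_ring)),
                  recursive = FALSE))
  }
  abort(sprintf("unsupported GeoJSON geometry type '%s' for a study area", type),
        class = "gwp_validation_error")
}

wkt_polygon_rings <- function(txt) {
  txt <- trimws(txt)
  kind <- toupper(sub("^\\s*([A-Za-z]+).*$", "\\1", txt))
  if (!kind %in% c("POLYGON", "MULTIPOLYGON")) {
    abort(sprintf("unsupported WKT geometry '%s'", kind), class = "gwp_validation_error")
  }
  body <- sub("^[A-Za-z]+\\s*", "", txt)
  ring_strings <- regmatches(body, gregexpr("\\(([^()]+)\\)", body))[[1]]
  if (length(ring_strings) == 0) {
    abort("no coordinate rings found in WKT", class = "gwp_io_error")
  }
  lapply(ring_strings, function(rs) {
    rs <- gsub("[()]", "", rs)
    parts <- strsplit(trimws(strsplit(rs, ",")[[1]]), "\\s+")
    x <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])), numeric(1))
    y <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])), numeric(1))
    if (anyNA(x) || anyNA(y)) {
      abort("non-numeric coordinates in WKT ring", class = "gwp_validation_error")
    }
    n <- length(x)
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
    list(x = x, y = y)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
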