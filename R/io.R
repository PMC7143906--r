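# GeoJSON / CSV writers and readers for blocks and point layers.

fmt_num <- function(x) {
  # fixed formatting so identical inputs give byte-identical files
  sub("\\.?0+$", "", sprintf("%.6f", x))
}

# Group a polyset's rings into GeoJSON MultiPolygon nesting: positive
# (counter-clockwise) rings are exteriors, each negative ring becomes a hole
# of the exterior containing its first vertex.
polyset_to_multipolygon <- function(rings) {
  areas <- vapply(rings, ring_signed_area, numeric(1))
  outers <- which(areas >= 0)
  holes <- which(areas < 0)
  if (length(outers) == 0) { outers <- seq_along(rings); holes <- integer(0) }
  polys <- lapply(outers, function(i) list(rings[[i]]))
  for (h in holes) {
    hx <- rings[[h]]$x[1]; hy <- rings[[h]]$y[1]
    owner <- 1L
    for (k in seq_along(outers)) {
      if (points_in_polyset(hx, hy, rings[outers[k]])) { owner <- k; break }
    }
    polys[[owner]] <- c(polys[[owner]], list(rings[[h]]))
  }
  polys
}

ring_json <- function(ring) {
  x <- c(ring$x, ring$x[1]); y <- c(ring$y, ring$y[1])  # close the ring
  paste0("[", paste0("[", fmt_num(x), ",", fmt_num(y), "]", collapse = ","), "]")
}

multipolygon_json <- function(rings) {
  polys <- polyset_to_multipolygon(rings)
  paste0("[",
         paste(vapply(polys, function(p) {
           paste0("[", paste(vapply(p, ring_json, character(1)), collapse = ","), "]")
         }, character(1)), collapse = ","),
         "]")
}

json_str <- function(x) {
  vapply(x, function(s) jsonlite::toJSON(unbox(s)), character(1))
}

unbox <- jsonlite::unbox

#' Write blocks to GeoJSON
#'
#' Writes a FeatureCollection with one MultiPolygon feature per block,
#' carrying `block_id`, `actual_area` and `merged_from` properties plus any
#' extra per-block columns supplied via `properties` (joined on `block_id`,
#' e.g. scores, classes, wells).
#'
#' @param blocks a `gw_blocks` tessellation.
#' @param path output file path.
#' @param properties optional data frame keyed by `block_id` with extra
#'   feature properties.
#' @return `path`, invisibly.
#' @export
write_blocks_geojson <- function(blocks, path, properties = NULL) {
  extra <- NULL
  if (!is.null(properties)) {
    extra <- as_tibble(properties)
    extra <- extra[match(blocks$block_id, extra$block_id),
                   setdiff(names(extra), "block_id"), drop = FALSE]
  }
  feats <- vapply(seq_len(nrow(blocks)), function(i) {
    props <- c(
      sprintf('"block_id":%s', json_str(blocks$block_id[i])),
      sprintf('"actual_area":%s', fmt_num(blocks$actual_area[i])),
      sprintf('"merged_from":[%s]',
              paste(json_str(blocks$merged_from[[i]]), collapse = ","))
    )
    if (!is.null(extra)) {
      for (nm in names(extra)) {
        v <- extra[[nm]][i]
        props <- c(props, sprintf('"%s":%s', nm,
                                  if (is.numeric(v)) fmt_num(v) else json_str(as.character(v))))
      }
    }
    paste0('{"type":"Feature","properties":{', paste(props, collapse = ","),
           '},"geometry":{"type":"MultiPolygon","coordinates":',
           multipolygon_json(blocks$geometry[[i]]), "}}")
  }, character(1))
  txt <- paste0('{"type":"FeatureCollection","features":[\n',
                paste(feats, collapse = ",\n"), "\n]}")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Read blocks back from GeoJSON
#'
#' Reads a FeatureCollection written by [write_blocks_geojson()] and returns
#' the per-block geometry and properties.
#'
#' @param path GeoJSON file path.
#' @return tibble with `block_id`, `geometry` (list-column of ring sets) and
#'   one column per scalar feature property.
#' @export
read_blocks_geojson <- function(path) {
  g <- parse_geojson(path)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    abort("expected a FeatureCollection of blocks", class = "gwp_validation_error")
  }
  rows <- lapply(g$features, function(f) {
    geom <- f$geometry
    rings <- switch(geom$type,
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly) {
        lapply(poly, function(cc) {
          r <- list(x = vapply(cc, function(p) as.numeric(p[[1]]), numeric(1)),
                    y = vapply(cc, function(p) as.numeric(p[[2]]), numeric(1)))
          n <- length(r$x)
          if (n > 1 && r$x[1] == r$x[n] && r$y[1] == r$y[n]) {
            r$x <- r$x[-n]; r$y <- r$y[-n]
          }
          r
        })
      }), recursive = FALSE),
      Polygon = geojson_polygon_rings(geom),
      abort(sprintf("unsupported block geometry '%s'", geom$type),
            class = "gwp_validation_error")
    )
    props <- f$properties
    scalars <- props[vapply(props, function(p) is.atomic(p) && length(p) == 1, logical(1))]
    c(list(geometry = list(rings)), scalars)
  })
  ids <- vapply(rows, function(r) as.character(r$block_id %||% NA_character_), character(1))
  out <- tibble(block_id = ids, geometry = lapply(rows, function(r) r$geometry[[1]]))
  prop_names <- setdiff(unique(unlist(lapply(rows, names))), c("geometry", "block_id"))
  for (nm in prop_names) {
    vals <- lapply(rows, function(r) r[[nm]] %||% NA)
    out[[nm]] <- simplify2array(vals)
  }
  out
}

#' Write a point table to GeoJSON
#'
#' One Point feature per row; non-coordinate columns become feature
#' properties.
#'
#' @param points tibble with `x`, `y` and optionally other columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(points, path) {
  points <- as_tibble(points)
  extra_cols <- setdiff(names(points), c("x", "y"))
  feats <- vapply(seq_len(nrow(points)), function(i) {
    props <- vapply(extra_cols, function(nm) {
      v <- points[[nm]][i]
      sprintf('"%s":%s', nm, if (is.numeric(v)) fmt_num(v) else json_str(as.character(v)))
    }, character(1))
    paste0('{"type":"Feature","properties":{', paste(props, collapse = ","),
           '},"geometry":{"type":"Point","coordinates":[',
           fmt_num(points$x[i]), ",", fmt_num(points$y[i]), "]}}")
  }, character(1))
  txt <- paste0('{"type":"FeatureCollection","features":[\n',
                paste(feats, collapse = ",\n"), "\n]}")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}
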