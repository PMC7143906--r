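# Block tessellation of the study area.
#
# Blocks are rows of a tibble with geometry in a list-column. Each block is
# the intersection of one or more half-open grid cells with the study-area
# polygon; merged blocks own several cells. Grid metadata (cell size, origin,
# the study area, cell-interface lengths) travels as attributes and is read
# back with grid_info().

cell_key <- function(row, col) sprintf("%d_%d", row, col)

block_id_for <- function(row, col, width) {
  sprintf("B%0*d-%0*d", width, row, width, col)
}

#' Tessellate a study area into grid blocks
#'
#' Lays an axis-aligned square grid over the study area, anchored at the
#' lower-left corner of its bounding box (plus an optional offset), and
#' returns every non-empty intersection of a cell with the area polygon as a
#' block. Cells are half-open, `[x0 + j d, x0 + (j+1) d) x [y0 + k d,
#' y0 + (k+1) d)`, so every point of the plane belongs to exactly one cell.
#'
#' @param area a [study_area()] (or a data frame / ring list coercible to one).
#' @param cell_size side length of a grid cell in metres (default 10 km).
#' @param origin_offset numeric length-2 offset, in metres, added to the
#'   bounding-box lower-left corner to shift the grid anchor.
#' @return a tibble of class `gw_blocks`, one row per block, with columns
#'   `block_id`, `row`, `col` (indices of the anchor cell), `geometry`
#'   (list-column of ring sets), `cells` (list-column of integer matrices of
#'   owned cell indices), `nominal_area` (`cell_size^2`), `actual_area`,
#'   `merged_from` (list-column of absorbed block ids, empty if none) and
#'   `neighbors` (list-column of adjacent block ids). Grid metadata is
#'   attached as attributes; see [grid_info()].
#' @examples
#' a <- study_area(data.frame(x = c(0, 20e3, 20e3, 0), y = c(0, 0, 20e3, 20e3)))
#' make_grid(a, 10e3)
#' @export
make_grid <- function(area, cell_size = 10000, origin_offset = c(0, 0)) {
  if (!inherits(area, "study_area")) area <- study_area(area)
  if (!is.numeric(cell_size) || length(cell_size) != 1 ||
      !is.finite(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be a single positive number of metres",
          class = "gwp_argument_error")
  }
  if (!is.numeric(origin_offset) || length(origin_offset) != 2 ||
      anyNA(origin_offset)) {
    abort("`origin_offset` must be two finite numbers", class = "gwp_argument_error")
  }
  d <- cell_size
  bb <- polyset_bbox(area$rings)
  # snap the origin so that cell (1,1) contains the bbox lower-left corner
  ox <- bb["xmin"] + origin_offset[1]
  oy <- bb["ymin"] + origin_offset[2]
  ox <- ox + floor((bb["xmin"] - ox) / d) * d
  oy <- oy + floor((bb["ymin"] - oy) / d) * d
  n_col <- max(1L, ceiling((bb["xmax"] - ox) / d - 1e-12))
  n_row <- max(1L, ceiling((bb["ymax"] - oy) / d - 1e-12))
  idw <- max(2L, nchar(as.character(max(n_row, n_col))))

  # ignore tangency slivers far below any physically meaningful fragment
  area_tol <- 1e-9 * d^2
  rows <- list()
  for (r in seq_len(n_row)) {
    for (cc in seq_len(n_col)) {
      cell <- rect_ring(ox + (cc - 1) * d, oy + (r - 1) * d,
                        ox + cc * d, oy + r * d)
      geom <- polyset_intersect(area$rings, list(cell))
      a <- polyset_area(geom)
      if (length(geom) > 0 && a > area_tol) {
        rows[[length(rows) + 1L]] <- list(row = r, col = cc, geometry = geom,
                                          actual_area = a)
      }
    }
  }
  if (length(rows) == 0) {
    abort("grid produced no blocks; is the study area degenerate?",
          class = "gwp_validation_error")
  }

  blocks <- tibble(
    block_id = vapply(rows, function(b) block_id_for(b$row, b$col, idw), character(1)),
    row = vapply(rows, `[[`, integer(1), "row"),
    col = vapply(rows, `[[`, integer(1), "col"),
    geometry = lapply(rows, `[[`, "geometry"),
    cells = lapply(rows, function(b) matrix(c(b$row, b$col), ncol = 2,
                                            dimnames = list(NULL, c("row", "col")))),
    nominal_area = d^2,
    actual_area = vapply(rows, `[[`, numeric(1), "actual_area"),
    merged_from = rep(list(character(0)), length(rows))
  )
  blocks <- blocks[order(blocks$block_id), ]

  edges <- compute_cell_edges(blocks, area$rings, ox, oy, d)
  attr(blocks, "gw_grid") <- list(
    cell_size = d, origin = c(x = unname(ox), y = unname(oy)),
    n_row = n_row, n_col = n_col, id_width = idw,
    area = area, cell_edges = edges
  )
  class(blocks) <- c("gw_blocks", class(tibble()))
  blocks$neighbors <- neighbor_lists(blocks)
  blocks
}

# Exact in-area lengths of every interface between occupied adjacent cells,
# via open-path clipping of the interface segment against the area polygon.
compute_cell_edges <- function(blocks, rings, ox, oy, d) {
  occ <- unique(do.call(rbind, blocks$cells))
  keys <- cell_key(occ[, "row"], occ[, "col"])
  occ_set <- stats::setNames(seq_along(keys), keys)
  out_a <- character(0); out_b <- character(0); out_len <- numeric(0)
  len_tol <- 1e-9 * d
  for (i in seq_len(nrow(occ))) {
    r <- occ[i, "row"]; cc <- occ[i, "col"]
    # right neighbour
    kr <- cell_key(r, cc + 1L)
    if (!is.na(occ_set[kr])) {
      x <- ox + cc * d
      len <- clipped_segment_length(x, oy + (r - 1) * d, x, oy + r * d, rings)
      if (len > len_tol) {
        out_a <- c(out_a, cell_key(r, cc)); out_b <- c(out_b, kr)
        out_len <- c(out_len, len)
      }
    }
    # top neighbour
    kt <- cell_key(r + 1L, cc)
    if (!is.na(occ_set[kt])) {
      y <- oy + r * d
      len <- clipped_segment_length(ox + (cc - 1) * d, y, ox + cc * d, y, rings)
      if (len > len_tol) {
        out_a <- c(out_a, cell_key(r, cc)); out_b <- c(out_b, kt)
        out_len <- c(out_len, len)
      }
    }
  }
  tibble(cell_a = out_a, cell_b = out_b, length = out_len)
}

#' Grid metadata of a block tessellation
#'
#' @param blocks a `gw_blocks` tibble from [make_grid()].
#' @return list with `cell_size`, `origin`, `n_row`, `n_col`, `area` (the
#'   [study_area()]), and `cell_edges` (in-area lengths of cell interfaces).
#' @export
grid_info <- function(blocks) {
  info <- attr(blocks, "gw_grid", exact = TRUE)
  if (is.null(info)) {
    abort("not a block tessellation: missing grid metadata (was it created by make_grid()?)",
          class = "gwp_argument_error")
  }
  info
}

# named vector: cell key -> owning block_id
cell_block_map <- function(blocks) {
  keys <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    m <- blocks$cells[[i]]
    cell_key(m[, "row"], m[, "col"])
  }))
  ids <- rep(blocks$block_id, vapply(blocks$cells, nrow, integer(1)))
  stats::setNames(ids, keys)
}

#' Block adjacency with shared-boundary lengths
#'
#' Two blocks are neighbours iff their shared boundary inside the study area
#' has positive length; touching at a corner does not count. The relation is
#' reported symmetrically (each pair appears in both directions).
#'
#' @param blocks a `gw_blocks` tibble.
#' @return tibble with columns `block_id`, `neighbor_id`, `shared_length`
#'   (metres), sorted by `block_id` then `neighbor_id`.
#' @export
block_adjacency <- function(blocks) {
  info <- grid_info(blocks)
  edges <- info$cell_edges
  if (nrow(edges) == 0) {
    return(tibble(block_id = character(0), neighbor_id = character(0),
                  shared_length = numeric(0)))
  }
  cmap <- cell_block_map(blocks)
  ba <- unname(cmap[edges$cell_a])
  bb <- unname(cmap[edges$cell_b])
  keep <- !is.na(ba) & !is.na(bb) & ba != bb
  pairs <- tibble(block_id = c(ba[keep], bb[keep]),
                  neighbor_id = c(bb[keep], ba[keep]),
                  shared_length = rep(edges$length[keep], 2))
  pairs |>
    dplyr::group_by(.data$block_id, .data$neighbor_id) |>
    dplyr::summarise(shared_length = sum(.data$shared_length), .groups = "drop") |>
    dplyr::arrange(.data$block_id, .data$neighbor_id)
}

neighbor_lists <- function(blocks) {
  adj <- block_adjacency(blocks)
  lapply(blocks$block_id, function(id) adj$neighbor_id[adj$block_id == id])
}

# Sentinel recorded in merged_from when an undersized block has no neighbour
# to merge into (e.g. an isolated islet block).
UNMERGEABLE <- ".unmergeable"

#' Merge undersized blocks into their neighbours
#'
#' Coastal clipping leaves some blocks much smaller than a full cell. Every
#' block whose area is at or below `min_area_fraction` of the nominal cell
#' area is
#' absorbed (geometry union) into the neighbour with which it shares the
#' longest in-area boundary; ties go to the smallest `block_id`. The process
#' iterates until no block is undersized. An undersized block with no
#' neighbour is kept and flagged with the sentinel `".unmergeable"` in
#' `merged_from`. Total area is conserved and the operation is idempotent.
#'
#' @param blocks a `gw_blocks` tibble from [make_grid()].
#' @param min_area_fraction blocks smaller than this fraction of
#'   `cell_size^2` are merged (default 0.5).
#' @return a `gw_blocks` tibble; absorbing blocks list the absorbed ids in
#'   `merged_from`.
#' @export
merge_small_blocks <- function(blocks, min_area_fraction = 0.5) {
  if (!is.data.frame(blocks) || nrow(blocks) == 0) {
    abort("`blocks` must be a non-empty block tessellation",
          class = "gwp_argument_error")
  }
  if (!is.numeric(min_area_fraction) || length(min_area_fraction) != 1 ||
      is.na(min_area_fraction) || min_area_fraction <= 0 || min_area_fraction >= 1) {
    abort("`min_area_fraction` must be in (0, 1)", class = "gwp_argument_error")
  }
  info <- grid_info(blocks)
  edges <- info$cell_edges
  df <- blocks
  threshold <- min_area_fraction * df$nominal_area[1]

  repeat {
    flagged <- vapply(df$merged_from, function(m) UNMERGEABLE %in% m, logical(1))
    und <- which(df$actual_area <= threshold * (1 + 1e-9) & !flagged)
    if (length(und) == 0) break
    i <- und[order(df$block_id[und])][1]
    sid <- df$block_id[i]
    scells <- cell_key(df$cells[[i]][, "row"], df$cells[[i]][, "col"])
    cmap <- cell_block_map(df)
    ea <- unname(cmap[edges$cell_a]); eb <- unname(cmap[edges$cell_b])
    touch <- (ea == sid) != (eb == sid)  # exactly one endpoint in this block
    touch[is.na(touch)] <- FALSE
    if (!any(touch)) {
      df$merged_from[[i]] <- unique(c(df$merged_from[[i]], UNMERGEABLE))
      next
    }
    other <- ifelse(ea[touch] == sid, eb[touch], ea[touch])
    shared <- tapply(edges$length[touch], other, sum)
    best_len <- max(shared)
    target_id <- min(names(shared)[shared >= best_len - 1e-9 * info$cell_size])
    j <- which(df$block_id == target_id)

    df$geometry[[j]] <- polyset_union(df$geometry[[j]], df$geometry[[i]])
    df$cells[[j]] <- rbind(df$cells[[j]], df$cells[[i]])
    df$actual_area[j] <- df$actual_area[j] + df$actual_area[i]
    df$merged_from[[j]] <- sort(unique(c(df$merged_from[[j]], sid,
                                         setdiff(df$merged_from[[i]], UNMERGEABLE))))
    df <- df[-i, ]
  }

  df <- df[order(df$block_id), ]
  attr(df, "gw_grid") <- info
  class(df) <- c("gw_blocks", class(tibble()))
  df$neighbors <- neighbor_lists(df)
  df
}

#' @export
print.gw_blocks <- function(x, ...) {
  info <- attr(x, "gw_grid", exact = TRUE)
  if (!is.null(info)) {
    cat(sprintf("<gw_blocks> %d block(s), cell %.0f m, grid %d x %d\n",
                nrow(x), info$cell_size, info$n_row, info$n_col))
  }
  NextMethod()
}
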