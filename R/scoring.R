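# Point-to-block assignment and the weighted pressure score.
#
# The score of a block is sum_i n_i * w_i over the twelve layers, where n_i
# is the number of points of pressure i falling in the block and w_i the
# layer's attributed weight. Containment only: a pressure influences the
# block it falls in, with no distance decay onto neighbours.

#' Assign pressure points to grid blocks
#'
#' Each point inside the study area is counted in exactly one block. The
#' half-open cell convention resolves points on interior grid lines (they
#' belong to the cell above/right); points whose cell is ambiguous after
#' clipping (e.g. exactly on the area boundary at the grid edge) are tested
#' against final block geometries in ascending `block_id` order and assigned
#' to the first containing block. Points outside the study area get
#' `block_id = NA` and their number is reported.
#'
#' @param points tibble with numeric `x`, `y` (and usually `layer`) columns.
#' @param blocks a `gw_blocks` tessellation from [make_grid()] /
#'   [merge_small_blocks()].
#' @param crs optional CRS identifier of the point coordinates; if supplied
#'   and different from the study area's, an error is raised (no silent
#'   reprojection).
#' @param quiet suppress the unassigned-point message.
#' @return the input tibble with a `block_id` column appended (`NA` for
#'   points outside the study area); the number of unassigned points is
#'   attached as attribute `"unassigned"`.
#' @export
assign_points <- function(points, blocks, crs = NULL, quiet = FALSE) {
  info <- grid_info(blocks)
  if (!is.null(crs) && !identical(crs, info$area$crs)) {
    abort(sprintf("point CRS '%s' does not match study-area CRS '%s'",
                  crs, info$area$crs), class = "gwp_validation_error")
  }
  points <- as_tibble(points)
  if (!all(c("x", "y") %in% names(points))) {
    abort("`points` needs numeric `x` and `y` columns", class = "gwp_argument_error")
  }
  n <- nrow(points)
  if (n == 0) {
    points$block_id <- character(0)
    attr(points, "unassigned") <- 0L
    return(points)
  }

  inside <- points_in_polyset(points$x, points$y, info$area$rings)
  d <- info$cell_size
  col <- floor((points$x - info$origin["x"]) / d) + 1L
  row <- floor((points$y - info$origin["y"]) / d) + 1L
  cmap <- cell_block_map(blocks)
  bid <- unname(cmap[cell_key(row, col)])
  bid[!inside] <- NA_character_

  # in-area points whose half-open cell produced no block: fall back to a
  # direct containment test in ascending block_id order
  odd <- which(inside & is.na(bid))
  for (i in odd) {
    for (j in seq_len(nrow(blocks))) {
      if (points_in_polyset(points$x[i], points$y[i], blocks$geometry[[j]])) {
        bid[i] <- blocks$block_id[j]
        break
      }
    }
  }

  points$block_id <- bid
  unassigned <- sum(is.na(bid))
  attr(points, "unassigned") <- unassigned
  if (unassigned > 0 && !quiet) {
    inform(sprintf("%d point(s) outside the study area were not assigned to any block",
                   unassigned))
  }
  points
}

#' Weighted pressure score from layer counts
#'
#' Evaluates `sum_i n_i w_i` for one block. Layers absent from `counts`
#' contribute zero.
#'
#' @param counts named numeric vector or `data.frame(layer, n)` of
#'   non-negative per-layer point counts; names must exist in the registry.
#' @param registry a `gw_registry` (default: [default_registry()]).
#' @return one-row tibble with `raw_total` (full precision) and `total`
#'   (rounded to 1 decimal, the reporting precision).
#' @examples
#' block_score(c(Sinkholes = 2, `Livestock farm` = 10))
#' @export
block_score <- function(counts, registry = default_registry()) {
  registry <- load_registry(registry)
  if (is.data.frame(counts)) {
    cn <- counts$n %||% counts$count
    counts <- stats::setNames(as.numeric(cn), counts$layer)
  }
  if (length(counts) > 0 && is.null(names(counts))) {
    abort("`counts` must be named by layer", class = "gwp_argument_error")
  }
  if (any(counts < 0)) {
    abort("negative layer count", class = "gwp_validation_error")
  }
  idx <- match_layers(names(counts), registry)
  raw <- sum(as.numeric(counts) * registry$weight[idx])
  tibble(raw_total = raw, total = round(raw, 1))
}

#' Score every block of a tessellation
#'
#' Assigns the points of all layers to blocks (unless a `block_id` column is
#' already present) and computes each block's weighted pressure score. Points
#' outside the study area are excluded from all scores.
#'
#' @param points tibble with `layer`, `x`, `y` columns (or pre-assigned with
#'   `block_id`).
#' @param blocks a `gw_blocks` tessellation.
#' @param registry a `gw_registry` (default: [default_registry()]).
#' @return tibble of class `gw_scores`: one row per block with `block_id`,
#'   one integer count column per registry layer (in registry order),
#'   `raw_total` and `total` (1-decimal reporting value). The registry and
#'   the unassigned-point count travel as attributes `"registry"` and
#'   `"unassigned"`.
#' @export
score_blocks <- function(points, blocks, registry = default_registry()) {
  registry <- load_registry(registry)
  points <- as_tibble(points)
  if (nrow(points) > 0 && !"layer" %in% names(points)) {
    abort("`points` needs a `layer` column", class = "gwp_argument_error")
  }
  if (nrow(points) > 0) {
    points$layer <- registry$layer[match_layers(points$layer, registry)]
  }
  if (!"block_id" %in% names(points)) {
    points <- assign_points(points, blocks, quiet = TRUE)
  }
  unassigned <- sum(is.na(points$block_id))

  counts <- points |>
    dplyr::filter(!is.na(.data$block_id)) |>
    dplyr::count(.data$block_id, .data$layer)
  grid_long <- tidyr::expand_grid(block_id = blocks$block_id, layer = registry$layer) |>
    dplyr::left_join(counts, by = c("block_id", "layer")) |>
    dplyr::mutate(n = as.integer(dplyr::coalesce(.data$n, 0L)))
  wide <- tidyr::pivot_wider(grid_long, names_from = "layer", values_from = "n")
  w <- stats::setNames(registry$weight, registry$layer)
  cnt_mat <- as.matrix(wide[, registry$layer, drop = FALSE])
  raw <- as.numeric(cnt_mat %*% w[registry$layer])
  out <- dplyr::bind_cols(wide, tibble(raw_total = raw, total = round(raw, 1))) |>
    dplyr::arrange(.data$block_id)
  attr(out, "registry") <- registry
  attr(out, "unassigned") <- unassigned
  class(out) <- c("gw_scores", class(tibble()))
  out
}

#' Long-format layer counts of a score table
#'
#' @param scores a `gw_scores` tibble from [score_blocks()].
#' @return tibble with `block_id`, `layer`, `n`.
#' @export
score_counts <- function(scores) {
  layer_cols <- setdiff(names(scores), c("block_id", "raw_total", "total"))
  tidyr::pivot_longer(as_tibble(scores)[, c("block_id", layer_cols)],
                      -"block_id", names_to = "layer", values_to = "n")
}
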