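# Pressure classes and monitoring-well allocation.
#
# Block scores are binned into K classes on half-open intervals of the
# 1-decimal reported score: class c covers (edge[c-1], edge[c]], with the
# first class extended down to zero (every block is monitored, even a
# hypothetical zero-score one) and the last class unbounded above. Each
# class carries a fixed number of monitoring wells per block.

#' Define a pressure-class scheme
#'
#' @param upper_edges strictly increasing upper score edges of classes
#'   `1..K-1`; class `K` is unbounded. Default `c(10, 20, 30)`: four classes
#'   covering (0, 10], (10, 20], (20, 30], (30, Inf) on scores rounded to 1
#'   decimal, with class 1 also absorbing scores below its nominal lower
#'   bound.
#' @param wells_per_class non-negative, non-decreasing integer wells per
#'   block for classes `1..K`. Default `1:4`.
#' @return list of class `class_scheme` with elements `upper_edges`,
#'   `wells_per_class`, `n_classes`.
#' @export
class_scheme <- function(upper_edges = c(10, 20, 30), wells_per_class = 1:4) {
  if (!is.numeric(upper_edges) || length(upper_edges) < 1 ||
      anyNA(upper_edges) || any(diff(upper_edges) <= 0)) {
    abort("`upper_edges` must be strictly increasing finite numbers",
          class = "gwp_validation_error")
  }
  k <- length(upper_edges) + 1L
  if (!is.numeric(wells_per_class) || length(wells_per_class) != k ||
      anyNA(wells_per_class) || any(wells_per_class < 0) ||
      any(wells_per_class != round(wells_per_class)) ||
      any(diff(wells_per_class) < 0)) {
    abort(sprintf(
      "`wells_per_class` must be %d non-negative, non-decreasing integers", k),
      class = "gwp_validation_error")
  }
  structure(list(upper_edges = as.numeric(upper_edges),
                 wells_per_class = as.integer(wells_per_class),
                 n_classes = k),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  lo <- c(0, x$upper_edges)
  hi <- c(x$upper_edges, Inf)
  cat(sprintf("<class_scheme> %d classes\n", x$n_classes))
  for (c in seq_len(x$n_classes)) {
    cat(sprintf("  class %d: (%g, %g]  ->  %d well(s) per block\n",
                c, lo[c], hi[c], x$wells_per_class[c]))
  }
  invisible(x)
}

#' Classify pressure scores
#'
#' Maps each score to its pressure class: the score is first rounded to 1
#' decimal (the reporting precision), then placed on half-open intervals
#' `(edge[c-1], edge[c]]`. Scores at or below the first edge — including
#' zero — fall in class 1. Monotone: a higher score never gets a lower
#' class, and every non-negative score maps to exactly one class.
#'
#' @param score numeric vector of non-negative block scores.
#' @param scheme a [class_scheme()].
#' @return integer vector of class indices in `1..K`.
#' @examples
#' classify_score(c(2.4, 10.0, 10.05, 42.5))
#' @export
classify_score <- function(score, scheme = class_scheme()) {
  if (!inherits(scheme, "class_scheme")) abort("`scheme` must be a class_scheme",
                                               class = "gwp_argument_error")
  if (any(score < 0, na.rm = TRUE)) {
    abort("scores must be non-negative", class = "gwp_validation_error")
  }
  r <- round(score, 1)
  out <- vapply(r, function(v) sum(v > scheme$upper_edges) + 1L, integer(1))
  out[is.na(score)] <- NA_integer_
  out
}

#' Allocate monitoring wells to blocks
#'
#' Attaches each block's pressure class and its fixed per-class number of
#' monitoring wells.
#'
#' @param scores a `gw_scores` tibble from [score_blocks()], or any data
#'   frame with `block_id` and `total` (or `raw_total`) columns.
#' @param scheme a [class_scheme()].
#' @return tibble of class `gw_allocation` with columns `block_id`, `total`,
#'   `pressure_class`, `n_wells`.
#' @export
allocate_wells <- function(scores, scheme = class_scheme()) {
  scores <- as_tibble(scores)
  if (nrow(scores) == 0) {
    out <- tibble(block_id = character(0), total = numeric(0),
                  pressure_class = integer(0), n_wells = integer(0))
    class(out) <- c("gw_allocation", class(out))
    return(out)
  }
  if (!"block_id" %in% names(scores)) {
    abort("`scores` needs a `block_id` column", class = "gwp_argument_error")
  }
  total <- if (!is.null(scores[["total"]])) {
    scores[["total"]]
  } else if (!is.null(scores[["raw_total"]])) {
    round(scores[["raw_total"]], 1)
  } else {
    abort("`scores` needs a `total` or `raw_total` column", class = "gwp_argument_error")
  }
  cls <- classify_score(total, scheme)
  out <- tibble(block_id = scores$block_id, total = total,
                pressure_class = cls,
                n_wells = scheme$wells_per_class[cls])
  class(out) <- c("gw_allocation", class(tibble()))
  attr(out, "scheme") <- scheme
  out
}

#' Per-class summary of a well allocation
#'
#' @param allocation a `gw_allocation` tibble from [allocate_wells()].
#' @param scheme the [class_scheme()] used (defaults to the one stored on
#'   the allocation).
#' @return tibble with one row per class (including empty classes):
#'   `pressure_class`, `n_blocks`, `wells_per_block`, `total_wells`; grand
#'   totals are attached as attributes `"total_blocks"` and `"total_wells"`.
#' @export
allocation_summary <- function(allocation, scheme = NULL) {
  scheme <- scheme %||% attr(allocation, "scheme", exact = TRUE) %||% class_scheme()
  per_class <- tibble(pressure_class = seq_len(scheme$n_classes),
                      wells_per_block = scheme$wells_per_class) |>
    dplyr::left_join(
      dplyr::count(as_tibble(allocation), .data$pressure_class, name = "n_blocks"),
      by = "pressure_class") |>
    dplyr::mutate(n_blocks = as.integer(dplyr::coalesce(.data$n_blocks, 0L)),
                  total_wells = .data$n_blocks * .data$wells_per_block) |>
    dplyr::select("pressure_class", "n_blocks", "wells_per_block", "total_wells")
  attr(per_class, "total_blocks") <- sum(per_class$n_blocks)
  attr(per_class, "total_wells") <- sum(per_class$total_wells)
  per_class
}

#' Suggest well coordinates inside blocks
#'
#' The per-class rule fixes how many wells a block receives; where exactly to
#' drill is outside the scoring model, so coordinate suggestions are an
#' optional convenience. `mode = "none"` (the default) adds no coordinates;
#' `"centroid"` places wells at the block centroid, deterministically
#' jittered onto distinct interior points when a block gets several wells
#' (falling back to an interior representative point for concave blocks
#' whose centroid lies outside); `"pressure_weighted"` puts wells at the
#' block's pressure points in decreasing order of layer weight, topping up
#' with centroid placement when a block holds fewer points than wells.
#'
#' @param allocation a `gw_allocation` from [allocate_wells()].
#' @param blocks the `gw_blocks` tessellation the allocation refers to.
#' @param mode `"none"`, `"centroid"` or `"pressure_weighted"`.
#' @param points assigned point table (required for `"pressure_weighted"`):
#'   needs `layer`, `x`, `y`, `block_id` columns.
#' @param registry registry supplying layer weights for
#'   `"pressure_weighted"`.
#' @param seed integer controlling the deterministic jitter sequence.
#' @return the allocation with a `wells` list-column of `tibble(x, y)` (one
#'   row per well, all inside the block geometry); absent for
#'   `mode = "none"`.
#' @export
place_wells <- function(allocation, blocks, mode = c("none", "centroid", "pressure_weighted"),
                        points = NULL, registry = default_registry(), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "none") return(allocation)
  if (mode == "pressure_weighted") {
    if (is.null(points) || !all(c("layer", "x", "y", "block_id") %in% names(points))) {
      abort("mode 'pressure_weighted' needs assigned `points` with layer/x/y/block_id",
            class = "gwp_argument_error")
    }
    registry <- load_registry(registry)
    points <- as_tibble(points)
    points$w <- registry$weight[match_layers(points$layer, registry)]
  }
  gi <- match(allocation$block_id, blocks$block_id)
  if (anyNA(gi)) {
    abort("allocation refers to block ids absent from `blocks`",
          class = "gwp_argument_error")
  }
  wells <- vector("list", nrow(allocation))
  for (i in seq_len(nrow(allocation))) {
    nw <- allocation$n_wells[i]
    geom <- blocks$geometry[[gi[i]]]
    sites <- tibble(x = numeric(0), y = numeric(0))
    if (nw > 0 && mode == "pressure_weighted") {
      bp <- points[!is.na(points$block_id) &
                     points$block_id == allocation$block_id[i], ]
      bp <- bp[order(-bp$w, bp$layer, bp$x, bp$y), ]
      take <- utils::head(unique(bp[, c("x", "y")]), nw)
      sites <- tibble(x = take$x, y = take$y)
    }
    if (nw > nrow(sites)) {
      sites <- dplyr::bind_rows(sites,
                                centroid_sites(geom, nw - nrow(sites), seed,
                                               avoid = sites))
    }
    wells[[i]] <- sites
  }
  allocation$wells <- wells
  allocation
}

# Deterministic distinct interior sites near the centroid: a golden-angle
# spiral of candidates with radius growing from ~1% of the block span,
# filtered to the block interior. The seed only rotates the spiral.
centroid_sites <- function(geom, n, seed, avoid = NULL) {
  if (n == 0) return(tibble(x = numeric(0), y = numeric(0)))
  anchor <- interior_point(geom)
  span <- sqrt(abs(polyset_area(geom)))
  taken <- if (is.null(avoid)) matrix(numeric(0), ncol = 2) else cbind(avoid$x, avoid$y)
  out_x <- numeric(0); out_y <- numeric(0)
  phi0 <- (seed %% 360) * pi / 180
  k <- 0L
  while (length(out_x) < n && k < 10000L) {
    if (k == 0L) {
      cand <- anchor
    } else {
      ang <- phi0 + k * 2.399963229728653  # golden angle
      rad <- 0.01 * span * sqrt(k)
      cand <- anchor + rad * c(cos(ang), sin(ang))
    }
    k <- k + 1L
    if (!points_in_polyset(cand[1], cand[2], geom)) next
    dup <- FALSE
    if (nrow(taken) > 0) {
      dup <- any((taken[, 1] - cand[1])^2 + (taken[, 2] - cand[2])^2 < (1e-9 * span)^2)
    }
    if (dup) next
    out_x <- c(out_x, cand[1]); out_y <- c(out_y, cand[2])
    taken <- rbind(taken, cand)
  }
  tibble(x = out_x, y = out_y)
}
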