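# Low-level planar geometry on ring lists.
#
# A "ring" is list(x =, y =) with no repeated closing vertex (the polyclip
# convention). A "polyset" is a list of rings interpreted with the even-odd
# fill rule: counter-clockwise rings are exterior boundaries, clockwise rings
# are holes. All polyclip output follows this orientation convention.

#' Signed area of a single ring (shoelace formula)
#'
#' Positive for counter-clockwise rings, negative for clockwise ones.
#' @param ring list with numeric `x` and `y` of equal length
#' @return signed area in squared coordinate units
#' @keywords internal
#' @noRd
ring_signed_area <- function(ring) {
  x <- ring$x
  y <- ring$y
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Area of a polyset under the even-odd rule
#' @keywords internal
#' @noRd
polyset_area <- function(rings) {
  if (length(rings) == 0) return(0)
  sum(vapply(rings, ring_signed_area, numeric(1)))
}

#' Bounding box of a polyset
#' @return named numeric `c(xmin, ymin, xmax, ymax)`
#' @keywords internal
#' @noRd
polyset_bbox <- function(rings) {
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Even-odd point-in-polyset test
#'
#' Points on any ring boundary count as inside. Vectorised over points.
#' @param x,y point coordinates
#' @param rings polyset
#' @return logical vector
#' @keywords internal
#' @noRd
points_in_polyset <- function(x, y, rings) {
  if (length(x) == 0) return(logical(0))
  crossings <- integer(length(x))
  on_edge <- logical(length(x))
  for (ring in rings) {
    res <- sp::point.in.polygon(x, y, ring$x, ring$y)
    crossings <- crossings + (res == 1L)
    on_edge <- on_edge | res >= 2L
  }
  on_edge | (crossings %% 2L == 1L)
}

#' Centroid of a polyset (area-weighted, even-odd)
#' @return numeric `c(x, y)`
#' @keywords internal
#' @noRd
polyset_centroid <- function(rings) {
  ax <- 0; ay <- 0; a <- 0
  for (ring in rings) {
    x <- ring$x; y <- ring$y
    n <- length(x)
    if (n < 3) next
    i2 <- c(2:n, 1L)
    cross <- x * y[i2] - x[i2] * y
    a <- a + sum(cross) / 2
    ax <- ax + sum((x + x[i2]) * cross) / 6
    ay <- ay + sum((y + y[i2]) * cross) / 6
  }
  if (abs(a) < .Machine$double.eps) {
    bb <- polyset_bbox(rings)
    return(c((bb["xmin"] + bb["xmax"]) / 2, (bb["ymin"] + bb["ymax"]) / 2))
  }
  unname(c(ax / a, ay / a))
}

#' Axis-aligned rectangle as a single counter-clockwise ring
#' @keywords internal
#' @noRd
rect_ring <- function(xmin, ymin, xmax, ymax) {
  list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# Clipper snaps coordinates to a grid of this resolution (metres). 1e-8 m
# keeps boolean-operation noise far below every tolerance in use while
# staying well inside 64-bit integer range for coordinates up to ~1e7 m.
CLIP_EPS <- 1e-8

#' Intersection of a polyset with another polyset (even-odd)
#' @keywords internal
#' @noRd
polyset_intersect <- function(a, b) {
  polyclip::polyclip(a, b, op = "intersection", eps = CLIP_EPS,
                     fillA = "evenodd", fillB = "evenodd")
}

#' Union of two polysets (even-odd)
#' @keywords internal
#' @noRd
polyset_union <- function(a, b) {
  polyclip::polyclip(a, b, op = "union", eps = CLIP_EPS,
                     fillA = "evenodd", fillB = "evenodd")
}

#' Total length of an open polyline clipped to a polyset
#'
#' Clips the path `(x1,y1)-(x2,y2)` against `rings` (even-odd fill) and
#' returns the summed length of the surviving pieces. Used for exact
#' shared-boundary lengths along grid lines.
#' @keywords internal
#' @noRd
clipped_segment_length <- function(x1, y1, x2, y2, rings) {
  seg <- list(list(x = c(x1, x2), y = c(y1, y2)))
  pieces <- polyclip::polyclip(seg, rings, op = "intersection", eps = CLIP_EPS,
                               closed = FALSE, fillB = "evenodd")
  if (length(pieces) == 0) return(0)
  sum(vapply(pieces, function(p) {
    dx <- diff(p$x); dy <- diff(p$y)
    sum(sqrt(dx^2 + dy^2))
  }, numeric(1)))
}

#' A representative interior point of a polyset
#'
#' Returns the centroid when it falls inside; otherwise scans a deterministic
#' grid of candidate points inside the bounding box and returns the interior
#' candidate closest to the centroid.
#' @keywords internal
#' @noRd
interior_point <- function(rings) {
  ctr <- polyset_centroid(rings)
  if (points_in_polyset(ctr[1], ctr[2], rings)) return(ctr)
  bb <- polyset_bbox(rings)
  for (res in c(11L, 31L, 101L)) {
    gx <- seq(bb["xmin"], bb["xmax"], length.out = res + 2L)[-c(1L, res + 2L)]
    gy <- seq(bb["ymin"], bb["ymax"], length.out = res + 2L)[-c(1L, res + 2L)]
    grid <- expand.grid(x = gx, y = gy)
    ok <- points_in_polyset(grid$x, grid$y, rings)
    if (any(ok)) {
      cand <- grid[ok, , drop = FALSE]
      d2 <- (cand$x - ctr[1])^2 + (cand$y - ctr[2])^2
      best <- which.min(d2)
      return(c(cand$x[best], cand$y[best]))
    }
  }
  ctr
}
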