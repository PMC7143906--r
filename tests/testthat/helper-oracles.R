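# Independent geometric oracles, written from first principles so they share
# no code path with the package implementation (which goes through Clipper).

# Ray-casting point-in-ring test, vectorised over points. Crossing-number
# algorithm with half-open edge treatment; boundary behaviour is undefined
# (oracle inputs are random interior points, never boundary points).
naive_pip <- function(px, py, ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Even-odd membership in a set of rings.
naive_in_polyset <- function(px, py, rings) {
  hits <- rep(0L, length(px))
  for (r in rings) hits <- hits + naive_pip(px, py, r)
  hits %% 2L == 1L
}

# Sutherland-Hodgman clipping of one ring by an axis-aligned rectangle
# (four half-plane clips). Returns the clipped ring; its shoelace area is
# exact even when bridge edges appear for concave subjects.
sh_clip_ring <- function(ring, xmin, ymin, xmax, ymax) {
  clip_halfplane <- function(pts, inside_fn, intersect_fn) {
    nx <- numeric(0); ny <- numeric(0)
    n <- length(pts$x)
    if (n == 0) return(list(x = nx, y = ny))
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      cur_in <- inside_fn(pts$x[i], pts$y[i])
      prev_in <- inside_fn(pts$x[j], pts$y[j])
      if (cur_in) {
        if (!prev_in) {
          p <- intersect_fn(pts$x[j], pts$y[j], pts$x[i], pts$y[i])
          nx <- c(nx, p[1]); ny <- c(ny, p[2])
        }
        nx <- c(nx, pts$x[i]); ny <- c(ny, pts$y[i])
      } else if (prev_in) {
        p <- intersect_fn(pts$x[j], pts$y[j], pts$x[i], pts$y[i])
        nx <- c(nx, p[1]); ny <- c(ny, p[2])
      }
    }
    list(x = nx, y = ny)
  }
  ix <- function(x1, y1, x2, y2, xc) c(xc, y1 + (y2 - y1) * (xc - x1) / (x2 - x1))
  iy <- function(x1, y1, x2, y2, yc) c(x1 + (x2 - x1) * (yc - y1) / (y2 - y1), yc)
  out <- ring
  out <- clip_halfplane(out, function(x, y) x >= xmin,
                        function(x1, y1, x2, y2) ix(x1, y1, x2, y2, xmin))
  out <- clip_halfplane(out, function(x, y) x <= xmax,
                        function(x1, y1, x2, y2) ix(x1, y1, x2, y2, xmax))
  out <- clip_halfplane(out, function(x, y) y >= ymin,
                        function(x1, y1, x2, y2) iy(x1, y1, x2, y2, ymin))
  out <- clip_halfplane(out, function(x, y) y <= ymax,
                        function(x1, y1, x2, y2) iy(x1, y1, x2, y2, ymax))
  out
}

shoelace <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# Brute-force scan of every bounding-box cell: clipped area of each cell
# against the polygon (signed shoelace of the Sutherland-Hodgman output,
# summed over rings). Returns a data frame of occupied cells.
brute_force_cell_scan <- function(rings, cell_size, area_tol = NULL) {
  xs <- unlist(lapply(rings, `[[`, "x")); ys <- unlist(lapply(rings, `[[`, "y"))
  x0 <- min(xs); y0 <- min(ys)
  nc <- ceiling((max(xs) - x0) / cell_size)
  nr <- ceiling((max(ys) - y0) / cell_size)
  if (is.null(area_tol)) area_tol <- 1e-9 * cell_size^2
  out <- NULL
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      a <- sum(vapply(rings, function(ring) {
        shoelace(sh_clip_ring(ring, x0 + (cc - 1) * cell_size, y0 + (r - 1) * cell_size,
                              x0 + cc * cell_size, y0 + r * cell_size))
      }, numeric(1)))
      if (a > area_tol) out <- rbind(out, data.frame(row = r, col = cc, area = a))
    }
  }
  out
}

# All-pairs shared-boundary oracle on final block geometries: sums collinear
# antiparallel overlaps between boundary edges of two ring sets.
edge_overlap_length <- function(rings_a, rings_b, tol = 1e-3) {
  segs <- function(rings) {
    do.call(rbind, lapply(rings, function(r) {
      n <- length(r$x)
      i2 <- c(2:n, 1L)
      cbind(x1 = r$x, y1 = r$y, x2 = r$x[i2], y2 = r$y[i2])
    }))
  }
  A <- segs(rings_a); B <- segs(rings_b)
  total <- 0
  for (i in seq_len(nrow(A))) {
    ax1 <- A[i, 1]; ay1 <- A[i, 2]; ax2 <- A[i, 3]; ay2 <- A[i, 4]
    dax <- ax2 - ax1; day <- ay2 - ay1
    la <- sqrt(dax^2 + day^2)
    if (la < tol) next
    ux <- dax / la; uy <- day / la
    for (j in seq_len(nrow(B))) {
      bx1 <- B[j, 1]; by1 <- B[j, 2]; bx2 <- B[j, 3]; by2 <- B[j, 4]
      # perpendicular distance of both B endpoints from line A
      d1 <- abs((bx1 - ax1) * uy - (by1 - ay1) * ux)
      d2 <- abs((bx2 - ax1) * uy - (by2 - ay1) * ux)
      if (d1 > tol || d2 > tol) next
      t1 <- (bx1 - ax1) * ux + (by1 - ay1) * uy
      t2 <- (bx2 - ax1) * ux + (by2 - ay1) * uy
      lo <- max(0, min(t1, t2)); hi <- min(la, max(t1, t2))
      if (hi > lo) total <- total + (hi - lo)
    }
  }
  total
}

# small convenience fixtures
square_area <- function(side = 20000, crs = "EPSG:3035") {
  study_area(data.frame(x = c(0, side, side, 0), y = c(0, 0, side, side)), crs = crs)
}

rect_area <- function(w, h, crs = "EPSG:3035") {
  study_area(data.frame(x = c(0, w, w, 0), y = c(0, 0, h, h)), crs = crs)
}

peninsula <- function() simulate_area("peninsula")

TABLE_COUNTS <- c(34L, 37L, 28L, 69L, 164L, 7L, 770L, 222L, 10L, 4L, 22L, 224L)
TABLE_TOTALS <- c(10.2, 29.6, 28, 55.2, 82, 7, 77, 44.4, 10, 0.8, 13.2, 179.2)
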