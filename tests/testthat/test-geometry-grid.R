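test_that("a square area tiles exactly into full cells", {
  g <- make_grid(square_area(20000), 10000)
  expect_equal(nrow(g), 4L)
  expect_equal(g$actual_area, rep(1e8, 4), tolerance = 1e-9)
  expect_equal(g$nominal_area, rep(1e8, 4))
  expect_true(all(lengths(g$merged_from) == 0))
})

test_that("a partial column yields an undersized block", {
  g <- make_grid(rect_area(25000, 10000), 10000)
  expect_equal(nrow(g), 3L)
  expect_equal(sort(g$actual_area), c(5e7, 1e8, 1e8), tolerance = 1e-9)
})

test_that("grid on the peninsula matches a brute-force half-plane clipping scan", {
  p <- peninsula()
  g <- make_grid(p, 10000)
  oracle <- brute_force_cell_scan(p$rings, 10000)
  expect_equal(nrow(g), nrow(oracle))
  got <- g[order(g$row, g$col), ]
  want <- oracle[order(oracle$row, oracle$col), ]
  expect_equal(got$row, want$row)
  expect_equal(got$col, want$col)
  expect_equal(got$actual_area, want$area, tolerance = 1e-6)
})

test_that("adjacency follows the rook rule on regular grids", {
  g <- make_grid(square_area(20000), 10000)   # 2 x 2
  adj <- block_adjacency(g)
  deg <- table(adj$block_id)
  expect_true(all(deg == 2))
  # corner contact only is not adjacency
  expect_false(any(adj$neighbor_id[adj$block_id == "B01-01"] == "B02-02"))

  strip <- make_grid(rect_area(30000, 10000), 10000)  # 1 x 3
  deg2 <- table(block_adjacency(strip)$block_id)
  expect_equal(unname(deg2[c("B01-01", "B01-02", "B01-03")]), c(1L, 2L, 1L),
               ignore_attr = TRUE)
})

test_that("adjacency is symmetric and matches the all-pairs edge-overlap oracle", {
  p <- peninsula()
  g <- merge_small_blocks(make_grid(p, 10000))
  adj <- block_adjacency(g)
  # symmetry
  key <- paste(adj$block_id, adj$neighbor_id)
  rev <- paste(adj$neighbor_id, adj$block_id)
  expect_setequal(key, rev)

  ids <- g$block_id
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      len <- edge_overlap_length(g$geometry[[i]], g$geometry[[j]])
      claimed <- adj$shared_length[adj$block_id == ids[i] & adj$neighbor_id == ids[j]]
      if (len > 1) {  # positive shared boundary (metre-scale tolerance)
        expect_length(claimed, 1L)
        expect_equal(claimed, len, tolerance = 1e-3)
      } else {
        expect_length(claimed, 0L)
      }
    }
  }
})

test_that("blocks tile the study area and have disjoint interiors", {
  p <- peninsula()
  g <- make_grid(p, 10000)
  m <- merge_small_blocks(g)
  expect_lt(abs(sum(g$actual_area) - p$area), 1e-6 * p$area)
  expect_lt(abs(sum(m$actual_area) - p$area), 1e-6 * p$area)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (j <= i) next
      ov <- gwpressure:::polyset_intersect(m$geometry[[i]], m$geometry[[j]])
      expect_lt(abs(gwpressure:::polyset_area(ov)), 1e-9 * m$nominal_area[1])
    }
  }
})

test_that("an undersized block merges into the neighbour with the longest shared boundary", {
  g <- make_grid(rect_area(25000, 10000), 10000)
  m <- merge_small_blocks(g, 0.5)
  expect_equal(nrow(m), 2L)
  absorber <- m[m$block_id == "B01-02", ]
  expect_equal(absorber$merged_from[[1]], "B01-03")
  expect_equal(absorber$actual_area, 1.5e8, tolerance = 1e-9)
  expect_equal(sum(m$actual_area), sum(g$actual_area))
})

test_that("merging is conservative, idempotent and a no-op on full grids", {
  full <- make_grid(square_area(30000), 10000)
  m0 <- merge_small_blocks(full)
  expect_equal(m0$block_id, full$block_id)
  expect_equal(m0$actual_area, full$actual_area)

  p <- peninsula()
  g <- make_grid(p, 10000)
  m1 <- merge_small_blocks(g)
  m2 <- merge_small_blocks(m1)
  expect_equal(sum(m1$actual_area), sum(g$actual_area), tolerance = 1e-12)
  expect_equal(m2$block_id, m1$block_id)
  expect_equal(m2$actual_area, m1$actual_area)
  expect_equal(m2$merged_from, m1$merged_from)
  # every undersized block was absorbed
  thr <- 0.5 * m1$nominal_area[1]
  expect_true(all(m1$actual_area >= thr))
})

test_that("an isolated undersized block is kept and flagged", {
  # two disjoint parts: a full 10 km cell and a far-away 2 km islet
  a <- study_area(list(
    list(x = c(0, 10e3, 10e3, 0), y = c(0, 0, 10e3, 10e3)),
    list(x = c(40e3, 42e3, 42e3, 40e3), y = c(0, 0, 2e3, 2e3))
  ))
  g <- make_grid(a, 10000)
  m <- merge_small_blocks(g, 0.5)
  expect_equal(nrow(m), 2L)
  islet <- m[m$actual_area < 1e7, ]
  expect_equal(islet$merged_from[[1]], gwpressure:::UNMERGEABLE)
  expect_equal(sum(m$actual_area), sum(g$actual_area))
})

test_that("gridding is deterministic and validates its arguments", {
  p <- peninsula()
  g1 <- make_grid(p, 10000)
  g2 <- make_grid(p, 10000)
  expect_equal(g1$block_id, g2$block_id)
  expect_equal(g1$geometry, g2$geometry)
  expect_equal(g1$actual_area, g2$actual_area)

  expect_error(make_grid(p, 0), class = "gwp_argument_error")
  expect_error(make_grid(p, -5), class = "gwp_argument_error")
  expect_error(merge_small_blocks(make_grid(p, 10000), 1.5),
               class = "gwp_argument_error")
  expect_error(merge_small_blocks(data.frame()), class = "gwp_argument_error")
})
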