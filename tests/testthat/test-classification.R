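test_that("scores fall into the published four-class bins", {
  expect_equal(classify_score(2.4), 1L)     # the observed minimum
  expect_equal(classify_score(42.5), 4L)    # the observed maximum
  expect_equal(classify_score(10.0), 1L)    # upper edge belongs to the class below
  expect_equal(classify_score(10.05), 2L)   # rounds to 10.1, above the edge
  expect_equal(classify_score(0), 1L)       # every block is monitored
  expect_equal(classify_score(c(9.96, 20.04, 20.06, 30.0, 30.1)),
               c(1L, 2L, 3L, 3L, 4L))
})

test_that("classification is monotone and partitions the non-negative scores", {
  s <- withr::with_seed(5, runif(500, 0, 60))
  cls <- classify_score(s)
  # independent binning oracle on the rounded score
  want <- as.integer(cut(round(s, 1), breaks = c(-Inf, 10, 20, 30, Inf)))
  expect_equal(cls, want)
  expect_true(all(cls >= 1 & cls <= 4))
  o <- order(s)
  expect_true(all(diff(cls[o]) >= 0))
  expect_error(classify_score(-1), class = "gwp_validation_error")
})

test_that("class schemes are validated", {
  expect_error(class_scheme(c(10, 10, 30)), class = "gwp_validation_error")
  expect_error(class_scheme(c(10, 20, 30), wells_per_class = c(1, 2, 3)),
               class = "gwp_validation_error")
  expect_error(class_scheme(c(10, 20, 30), wells_per_class = c(4, 3, 2, 1)),
               class = "gwp_validation_error")
  expect_error(class_scheme(c(10, 20, 30), wells_per_class = c(1, 2, 3, 4.5)),
               class = "gwp_validation_error")
  sch <- class_scheme(c(5, 15), wells_per_class = c(0, 2, 6))
  expect_equal(sch$n_classes, 3L)
  expect_equal(classify_score(c(3, 7, 40), sch), c(1L, 2L, 3L))
})

test_that("the per-class well rule reproduces the published allocation arithmetic", {
  # the published per-class block counts: 11, 9, 8 and 4 blocks
  scores <- tibble::tibble(
    block_id = sprintf("B%02d", 1:32),
    total = c(rep(5, 11), rep(15, 9), rep(25, 8), rep(35, 4))
  )
  alloc <- allocate_wells(scores)
  smry <- allocation_summary(alloc)
  expect_equal(smry$n_blocks, c(11L, 9L, 8L, 4L))
  expect_equal(smry$total_wells, c(11L, 18L, 24L, 16L))
  expect_equal(attr(smry, "total_wells"), 69L)
  expect_equal(attr(smry, "total_blocks"), 32L)
  # sum over blocks equals the per-class arithmetic
  expect_equal(sum(alloc$n_wells),
               sum(smry$n_blocks * smry$wells_per_block))
})

test_that("degenerate allocations behave", {
  # all blocks in class 1: one well per block
  alloc <- allocate_wells(tibble::tibble(block_id = c("a", "b"), total = c(1, 2)))
  expect_equal(alloc$n_wells, c(1L, 1L))
  # empty input: empty allocation
  empty <- allocate_wells(tibble::tibble(block_id = character(0), total = numeric(0)))
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(allocation_summary(empty)), 4L)
  expect_equal(attr(allocation_summary(empty), "total_wells"), 0L)
})

test_that("suggested well sites are deterministic and inside their blocks", {
  g <- make_grid(square_area(20000), 10000)
  scores <- score_blocks(tibble::tibble(
    layer = rep("Potentially Contaminated Sites", 35),
    x = withr::with_seed(3, runif(35, 0, 10000)),
    y = withr::with_seed(4, runif(35, 0, 10000))), g)
  alloc <- allocate_wells(scores)

  none <- place_wells(alloc, g, mode = "none")
  expect_false("wells" %in% names(none))

  cen <- place_wells(alloc, g, mode = "centroid", seed = 7)
  expect_equal(vapply(cen$wells, nrow, integer(1)), alloc$n_wells)
  # a single well in a convex block sits at the centroid
  one <- cen$wells[[which(alloc$n_wells == 1)[1]]]
  blk <- g$geometry[[which(alloc$n_wells == 1)[1]]]
  expect_equal(c(one$x, one$y), gwpressure:::polyset_centroid(blk), tolerance = 1e-9)
  for (i in seq_len(nrow(cen))) {
    w <- cen$wells[[i]]
    if (nrow(w) == 0) next
    expect_true(all(gwpressure:::points_in_polyset(w$x, w$y, g$geometry[[i]])))
    expect_equal(nrow(unique(w)), nrow(w))  # distinct sites
  }
  cen2 <- place_wells(alloc, g, mode = "centroid", seed = 7)
  expect_identical(cen$wells, cen2$wells)

  pts <- assign_points(tibble::tibble(layer = "Sinkholes", x = 2000, y = 3000), g)
  pw <- place_wells(alloc, g, mode = "pressure_weighted", points = pts, seed = 1)
  # the sinkhole point anchors a well in its block
  i <- which(alloc$block_id == "B01-01")
  expect_true(any(pw$wells[[i]]$x == 2000 & pw$wells[[i]]$y == 3000))
  expect_error(place_wells(alloc, g, mode = "pressure_weighted"),
               class = "gwp_argument_error")
})
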