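test_that("points land in the block that contains them", {
  g <- make_grid(square_area(20000), 10000)
  pts <- tibble::tibble(layer = "Sinkholes", x = 2500, y = 2500)
  got <- assign_points(pts, g)
  expect_equal(got$block_id, "B01-01")

  sc <- score_blocks(got, g)
  expect_equal(sc$total[sc$block_id == "B01-01"], 0.8)
  expect_equal(sc$total[sc$block_id != "B01-01"], rep(0, 3))
})

test_that("a point on a shared cell edge is counted exactly once (half-open rule)", {
  g <- make_grid(square_area(20000), 10000)
  # on the interior vertical grid line: belongs to the right-hand cell
  pts <- tibble::tibble(layer = "Sinkholes", x = c(10000, 5000), y = c(5000, 10000))
  got <- assign_points(pts, g)
  expect_equal(got$block_id, c("B01-02", "B02-01"))
  expect_equal(sum(!is.na(got$block_id)), 2L)
})

test_that("points outside the study area are reported, not scored", {
  g <- make_grid(square_area(20000), 10000)
  pts <- tibble::tibble(layer = "Sinkholes",
                        x = c(5000, -5000, 25000), y = c(5000, 5000, 5000))
  expect_message(got <- assign_points(pts, g), "2 point")
  expect_equal(attr(got, "unassigned"), 2L)
  expect_true(is.na(got$block_id[2]) && is.na(got$block_id[3]))
  sc <- score_blocks(got, g)
  expect_equal(sum(sc$raw_total), 0.8)
  # a declared CRS mismatch is an error
  expect_error(assign_points(pts, g, crs = "EPSG:25832"),
               class = "gwp_validation_error")
})

test_that("assignment matches the naive all-pairs point-in-polygon oracle", {
  p <- peninsula()
  blocks <- merge_small_blocks(make_grid(p, 10000))
  bb <- gwpressure:::polyset_bbox(p$rings)
  for (seed in 1:3) {
    pts <- withr::with_seed(seed, {
      n <- 1000
      tibble::tibble(layer = "Sinkholes",
                     x = runif(n, bb["xmin"], bb["xmax"]),
                     y = runif(n, bb["ymin"], bb["ymax"]))
    })
    got <- assign_points(pts, blocks, quiet = TRUE)
    want <- rep(NA_character_, nrow(pts))
    for (i in order(blocks$block_id)) {
      hit <- naive_in_polyset(pts$x, pts$y, blocks$geometry[[i]])
      want[hit & is.na(want)] <- blocks$block_id[i]
    }
    expect_equal(got$block_id, want)
  }
})

test_that("block scores evaluate the weighted count sum", {
  bs <- block_score(c(Sinkholes = 2, `Livestock farm` = 10))
  expect_equal(bs$raw_total, 2.6)
  expect_equal(block_score(c(`Potentially Contaminated Sites` = 28))$total, 28.0)
  expect_equal(block_score(stats::setNames(numeric(0), character(0)))$raw_total, 0)
  expect_error(block_score(c(Sinkholes = -1)), class = "gwp_validation_error")
  expect_error(block_score(c(`No Such Layer` = 3)), class = "gwp_validation_error")
  # layer names match case-insensitively with whitespace normalisation
  expect_equal(block_score(c(`  sinkholes ` = 1))$raw_total, 0.8)
})

test_that("scores are conserved, additive and permutation invariant", {
  p <- peninsula()
  blocks <- merge_small_blocks(make_grid(p, 10000))
  pts <- simulate_layers(p, seed = 11)
  sc <- score_blocks(pts, blocks)
  w <- default_registry()$weight
  expect_lt(abs(sum(sc$raw_total) - sum(TABLE_COUNTS * w)), 1e-9)

  # permutation invariance: shuffled points, same scores
  pts2 <- withr::with_seed(99, pts[sample.int(nrow(pts)), ])
  sc2 <- score_blocks(pts2, blocks)
  expect_equal(as.data.frame(sc2), as.data.frame(sc))

  # additivity: moving one sinkhole point between blocks shifts 0.8
  ctrs <- lapply(blocks$geometry[1:2], gwpressure:::interior_point)
  base <- tibble::tibble(layer = "Sinkholes", x = ctrs[[1]][1], y = ctrs[[1]][2])
  moved <- tibble::tibble(layer = "Sinkholes", x = ctrs[[2]][1], y = ctrs[[2]][2])
  s1 <- score_blocks(base, blocks)
  s2 <- score_blocks(moved, blocks)
  delta <- s2$raw_total - s1$raw_total
  expect_equal(delta[1], -0.8)
  expect_equal(delta[2], 0.8)
  expect_true(all(delta[-(1:2)] == 0))

  # monotonicity: adding a point never decreases any score
  extra <- rbind(pts, tibble::tibble(layer = "Urban solid waste landfill",
                                     x = ctrs[[1]][1], y = ctrs[[1]][2]))
  s3 <- score_blocks(extra, blocks)
  expect_true(all(s3$raw_total >= sc$raw_total))
})

test_that("empty layers give zero scores everywhere", {
  g <- make_grid(square_area(20000), 10000)
  sc <- score_blocks(tibble::tibble(layer = character(0), x = numeric(0), y = numeric(0)), g)
  expect_equal(sc$raw_total, rep(0, 4))
  expect_equal(unname(as.matrix(sc[, default_registry()$layer])),
               matrix(0L, 4, 12), ignore_attr = TRUE)
})
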