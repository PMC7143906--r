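test_that("the default registry carries the twelve weighted layers", {
  reg <- default_registry()
  expect_equal(nrow(reg), 12L)
  expect_equal(reg$weight[reg$layer == "Sinkholes"], 0.8)
  expect_equal(reg$weight[reg$layer == "Livestock farm"], 0.1)
  expect_equal(reg$weight[reg$layer == "Potentially Contaminated Sites"], 1)
  expect_true(all(reg$weight >= 0 & reg$weight <= 1))
  # sinkholes are the single natural pressure
  expect_equal(reg$layer[reg$kind == "natural"], "Sinkholes")
  expect_identical(load_registry("default"), reg)
})

test_that("registry validation rejects bad weights and duplicate names", {
  expect_error(load_registry(data.frame(layer = "X", weight = 1.3)),
               class = "gwp_validation_error")
  expect_error(load_registry(data.frame(layer = "X", weight = -0.1)),
               class = "gwp_validation_error")
  expect_error(
    load_registry(data.frame(layer = c("Quarry", " quarry "), weight = c(0.2, 0.3))),
    class = "gwp_validation_error")

  # custom registries load from data frames and CSV with a `name` column
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,weight,kind", "Springs,0.4,natural", "Mills,0.2,anthropic"), f)
  reg <- load_registry(f)
  expect_equal(reg$layer, c("Springs", "Mills"))
  expect_equal(reg$weight, c(0.4, 0.2))
})

test_that("point files load from CSV and GeoJSON, keeping duplicates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "100,200", "300,400", "100,200"), f)
  pts <- suppressMessages(load_points(f, "Sinkholes"))
  expect_equal(nrow(pts), 3L)                     # exact duplicates retained
  expect_equal(pts$layer, rep("Sinkholes", 3))
  expect_equal(pts$x, c(100, 300, 100))

  gj <- tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","properties":{},"geometry":{"type":"Point","coordinates":[5,6]}},',
    '{"type":"Feature","properties":{},"geometry":{"type":"Point","coordinates":[7,8]}}]}'), gj)
  pts2 <- suppressMessages(load_points(gj, "Active quarries"))
  expect_equal(nrow(pts2), 2L)
  expect_equal(pts2$y, c(6, 8))

  # a non-Point feature is an error naming the offending index
  bad <- tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","properties":{},"geometry":{"type":"Point","coordinates":[5,6]}},',
    '{"type":"Feature","properties":{},"geometry":{"type":"LineString","coordinates":[[0,0],[1,1]]}}]}'), bad)
  expect_error(suppressMessages(load_points(bad, "Sinkholes")), "feature 2",
               class = "gwp_validation_error")

  badcsv <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "a,b"), badcsv)
  expect_error(suppressMessages(load_points(badcsv, "Sinkholes")),
               class = "gwp_validation_error")
  expect_error(load_points(tempfile(), "Sinkholes"), class = "gwp_io_error")
})

test_that("per-layer totals reproduce the published count-weight products", {
  reg <- default_registry()
  pts <- tibble::tibble(layer = rep(reg$layer, TABLE_COUNTS))
  lsum <- layer_summary(pts, reg)
  expect_equal(lsum$n, TABLE_COUNTS)
  expect_equal(round(lsum$total_score, 1), TABLE_TOTALS)
  expect_equal(layer_total_score(224, 0.8), 179.2)
  expect_equal(layer_total_score(770, 0.1), 77)
  expect_equal(layer_total_score(0, 0.9), 0)
})

test_that("layer totals are linear in point count", {
  n <- c(3, 17, 40)
  w <- c(0.2, 0.5, 1)
  expect_equal(layer_total_score(2 * n, w), 2 * layer_total_score(n, w))
  expect_error(layer_total_score(-1, 0.5), class = "gwp_validation_error")
  # unknown layer names in a point table are an error, not a new layer
  expect_error(layer_summary(tibble::tibble(layer = "Windmills")),
               class = "gwp_validation_error")
})
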