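test_that("ASCII grid read translates nodata and survives a write/read round trip", {
  g <- tiny_grid(c(30, 31, 32, NA))
  expect_equal(sum(is.finite(g$values)), 3)
  expect_true(is.na(g$values[2, 2]))

  p <- withr::local_tempfile(fileext = ".asc")
  write_climate_grid(g, p)
  g2 <- read_climate_grid(p, label = "test")
  expect_identical(g2$values, g$values)
  expect_equal(g2$xmin, g$xmin)
  expect_equal(g2$cellsize, g$cellsize)

  # second round trip is bit-for-bit stable
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_climate_grid(g2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("scaled-integer storage is undone by the scale config", {
  base <- make_baseline(nrow = 8, ncol = 6, noise_sd = 0.3, seed = 9)
  scaled <- base
  scaled$values <- round(base$values * 10)
  p <- withr::local_tempfile(fileext = ".asc")
  write_climate_grid(scaled, p)
  g <- read_climate_grid(p, scale = 0.1)
  expect_equal(g$values, round(base$values * 10) / 10, tolerance = 1e-6)
})

test_that("unreadable and degenerate grids are rejected", {
  expect_error(read_climate_grid("no/such/file.asc"), "cannot read")
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "-9999 -9999"), p)
  expect_error(read_climate_grid(p), "nodata")
  expect_error(climate_grid(matrix(NA_real_, 2, 2)), "empty grid")
})

test_that("assemble_scenarios enforces alignment and unions nodata masks", {
  b <- tiny_grid(1:12, nrow = 3, ncol = 4)
  futs <- lapply(1:15, function(i) {
    g <- b; g$values <- b$values + i; g$label <- paste0("GCM", i, "xSSP")
    g
  })
  ss <- assemble_scenarios(b, futs)
  expect_s3_class(ss, "scenario_set")
  expect_equal(n_scenarios(ss), 15)

  bad <- tiny_grid(1:6, nrow = 2, ncol = 3)
  expect_error(assemble_scenarios(b, list(bad)), "alignment")
  shifted <- b; shifted$xmin <- b$xmin + 0.5
  expect_error(assemble_scenarios(b, list(shifted)), "alignment")

  # disjoint nodata cells: combined mask is the union
  f1 <- b; f1$values[1, 1] <- NA
  f2 <- b; f2$values[3, 4] <- NA
  ss2 <- assemble_scenarios(b, list(f1, f2))
  for (g in c(list(ss2$baseline), ss2$futures)) {
    expect_true(is.na(g$values[1, 1]))
    expect_true(is.na(g$values[3, 4]))
    expect_equal(sum(is.finite(g$values)), 10)
  }
})

test_that("assembling an already-assembled set changes nothing", {
  b <- tiny_grid(1:12, nrow = 3, ncol = 4)
  f <- b; f$values <- b$values + 2; f$label <- "AxB"
  ss <- assemble_scenarios(b, list(f))
  expect_identical(assemble_scenarios(ss), ss)
  ss2 <- assemble_scenarios(ss$baseline, ss$futures,
                            gcm = ss$labels$gcm, ssp = ss$labels$ssp)
  expect_identical(ss2$baseline$values, ss$baseline$values)
  expect_identical(ss2$futures[[1]]$values, ss$futures[[1]]$values)
})

test_that("read_ranges pairs epochs, drops incomplete species, repairs bow-ties", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(species_id = "sp1", epoch = "historical"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(4, 0),
                                                   list(4, 4), list(0, 4),
                                                   list(0, 0))))),
      list(type = "Feature",
           properties = list(species_id = "sp1", epoch = "current"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(1, 1), list(3, 1),
                                                   list(3, 3), list(1, 3),
                                                   list(1, 1))))),
      # bow-tie ring: (0,0) (2,2) (2,0) (0,2) - self-intersecting
      list(type = "Feature",
           properties = list(species_id = "sp2", epoch = "historical"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(2, 2),
                                                   list(2, 0), list(0, 2),
                                                   list(0, 0))))),
      list(type = "Feature",
           properties = list(species_id = "sp2", epoch = "current"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(1, 1),
                                                   list(1, 0), list(0, 1),
                                                   list(0, 0))))),
      list(type = "Feature",
           properties = list(species_id = "sp3", epoch = "historical"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(1, 0),
                                                   list(1, 1), list(0, 0)))))
    ))
  p <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, p, auto_unbox = TRUE, digits = NA)

  expect_warning(rr <- read_ranges(p), "sp3")
  expect_named(rr, c("sp1", "sp2"))

  # bow-tie interpreted as its two triangles: (0,0)(0,2)(1,1) + (2,0)(2,2)(1,1)
  tri_area <- shoelace(cbind(c(0, 0, 1), c(0, 2, 1))) +
    shoelace(cbind(c(2, 2, 1), c(0, 2, 1)))
  expect_equal(poly_area(rr$sp2$historical), tri_area)
  expect_gt(poly_area(rr$sp2$historical), 0)
})

test_that("range files missing required attributes are a schema error", {
  gj <- list(type = "FeatureCollection",
             features = list(list(type = "Feature",
                                  properties = list(species_id = "x"),
                                  geometry = list(type = "Polygon",
                                                  coordinates = list()))))
  p <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, p, auto_unbox = TRUE)
  expect_error(read_ranges(p), "schema error")
})

test_that("range round trip through GeoJSON preserves geometry", {
  rg <- species_range("sp", rect_poly(0, 0, 5, 5), rect_poly(1, 1, 3, 4))
  p <- withr::local_tempfile(fileext = ".geojson")
  write_ranges(list(rg), p)
  rr <- read_ranges(p)
  expect_equal(poly_area(rr$sp$historical), 25)
  expect_equal(poly_area(rr$sp$current), 6)
})
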