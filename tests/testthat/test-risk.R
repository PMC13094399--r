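test_that("overlap_percent counts the within-envelope fraction", {
  env <- compute_envelope(value_sample(c(30, 40)), "current")
  s_min <- value_sample(rep(30, 5))
  expect_equal(overlap_percent(s_min, env, "upper"), 100)
  expect_equal(overlap_percent(s_min, env, "two_sided"), 100)

  s <- value_sample(c(38, 39, 40, 41, 42))
  expect_equal(overlap_percent(s, env, "upper"), 60)  # 3 of 5 <= 40

  # counting oracle on random values and envelopes, both modes
  set.seed(11)
  for (i in 1:5) {
    v <- runif(1000, 0, 60)
    lo <- runif(1, 10, 30); hi <- lo + runif(1, 1, 20)
    env_r <- compute_envelope(value_sample(c(lo, hi)), "historical")
    n_up <- 0; n_two <- 0
    for (x in v) {  # brute-force loop
      if (x <= hi) n_up <- n_up + 1
      if (x >= lo && x <= hi) n_two <- n_two + 1
    }
    sv <- value_sample(v)
    expect_equal(overlap_percent(sv, env_r, "upper"), 100 * n_up / 1000)
    expect_equal(overlap_percent(sv, env_r, "two_sided"), 100 * n_two / 1000)
  }
})

test_that("overlap weights shift the percentage as weighted fractions", {
  env <- compute_envelope(value_sample(c(0, 10)), "current")
  s <- value_sample(c(5, 15), weights = c(3, 1))
  expect_equal(overlap_percent(s, env), 75)
})

test_that("no warming gives 100% overlap, extreme warming 0%, both SE 0", {
  g <- make_baseline(nrow = 12, ncol = 12, noise_sd = 0.5, seed = 2)
  rg <- species_range("sp", rect_poly(115, -38, 118, -35.5),
                      rect_poly(115.5, -37.5, 117, -36))
  same <- lapply(1:3, function(i) {
    f <- g; f$label <- paste0("G", i, "xS"); f
  })
  ov <- summarise_overlaps(rg, assemble_scenarios(g, same))
  expect_equal(ov$mean_current, 100)
  expect_equal(ov$mean_historical, 100)
  expect_equal(ov$se_current, 0)
  expect_equal(ov$se_historical, 0)

  hot <- g; hot$values <- g$values + 100; hot$label <- "GxS"
  ov2 <- summarise_overlaps(rg, assemble_scenarios(g, list(hot)))
  expect_equal(ov2$mean_current, 0)
  expect_equal(ov2$mean_historical, 0)
})

test_that("a fixed warmed mask over 40% of current cells gives mean 60%, SE 0", {
  g <- make_baseline(nrow = 10, ncol = 10, seed = 1,
                     xmin = 0, ymin = 0, cellsize = 1)
  # current range: one row of 10 cells; warm exactly 4 of them in every scenario
  curr_cells <- data.frame(row = 5, col = 1:10)
  rg <- species_range("sp",
                      historical = cells_to_poly(expand.grid(row = 4:6, col = 1:10), g),
                      current = cells_to_poly(curr_cells, g))
  futures <- lapply(1:5, function(i) {
    f <- g
    f$values[5, 1:4] <- f$values[5, 1:4] + 100
    f$label <- paste0("G", i, "xS")
    f
  })
  ov <- summarise_overlaps(rg, assemble_scenarios(g, futures))
  expect_equal(ov$mean_current, 60)
  expect_equal(ov$se_current, 0)
})

test_that("risk tiers follow the threshold rules with the SE upgrade", {
  mk <- function(mc, sec, mh, seh) {
    structure(list(species_id = "x",
                   per_scenario = tibble::tibble(scenario = 1:15),
                   mean_current = mc, se_current = sec,
                   mean_historical = mh, se_historical = seh,
                   mode = "upper"),
              class = "overlap_summary")
  }
  expect_equal(as.character(classify_risk(mk(80, 1, 90, 1))$tier), "low")
  expect_equal(as.character(classify_risk(mk(30, 1, 80, 1))$tier), "moderate")
  expect_equal(as.character(classify_risk(mk(30, 1, 40, 1))$tier), "high")

  # SE crossing the criterion upgrades: 52 - 3 <= 50
  r <- classify_risk(mk(52, 3, 90, 1))
  expect_equal(as.character(r$tier), "moderate")
  expect_true(r$upgraded)
  r2 <- classify_risk(mk(80, 1, 90, 1))
  expect_false(r2$upgraded)
  # ties at exactly the threshold fail the strict criterion
  r3 <- classify_risk(mk(50, 0, 90, 0))
  expect_equal(as.character(r3$tier), "moderate")
  expect_false(r3$upgraded)
  # upgrade can span two tiers when both SEs cross
  r4 <- classify_risk(mk(51, 2, 51, 2))
  expect_equal(as.character(r4$tier), "high")
  expect_true(r4$upgraded)
})

test_that("historical overlap dominates current overlap for nested ranges", {
  sc <- test_world()
  sp <- make_species(sc, "moderate", seed = 77)
  ov <- summarise_overlaps(sp$range, sc)
  expect_true(all(ov$per_scenario$pct_historical >= ov$per_scenario$pct_current))
})

test_that("uniform extra warming never lowers the risk tier", {
  sc <- test_world()
  sp <- make_species(sc, "low", seed = 19)
  tiers <- vapply(c(0, 2, 4, 8), function(off) {
    futs <- lapply(sc$futures, function(f) {
      f$values <- f$values + off
      f
    })
    sc2 <- assemble_scenarios(sc$baseline, futs,
                              gcm = sc$labels$gcm, ssp = sc$labels$ssp)
    as.character(classify_risk(summarise_overlaps(sp$range, sc2))$tier)
  }, character(1))
  ranks <- match(tiers, c("low", "moderate", "high"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("refugia categories match an exhaustive cell-by-scenario oracle", {
  set.seed(55)
  g <- make_baseline(nrow = 15, ncol = 15, noise_sd = 1, seed = 6,
                     xmin = 0, ymin = 0, cellsize = 1)
  futures <- lapply(1:4, function(i) {
    f <- g
    f$values <- f$values + matrix(runif(225, 0, 6), 15, 15)
    f$label <- paste0("G", i, "xS")
    f
  })
  sc <- assemble_scenarios(g, futures)
  rg <- species_range("sp", rect_poly(2, 2, 13, 12), rect_poly(4, 4, 9, 8))
  rf <- refugia_map(rg, sc)

  samp <- extract_cell_values(g, rg$historical)
  tm <- max(samp$values)
  for (i in seq_len(samp$n_cells)) {           # triple loop oracle
    r <- samp$cells$row[i]; cl <- samp$cells$col[i]
    n_below <- 0
    for (f in sc$futures) if (f$values[r, cl] <= tm) n_below <- n_below + 1
    expected <- if (n_below == 4) 1L else if (n_below > 0) 2L else 3L
    expect_identical(rf$categories[r, cl], expected)
  }
  # cells outside the polygon are 'outside'
  expect_identical(rf$categories[1, 1], 0L)
  expect_equal(sum(rf$area_fractions$fraction), 1, tolerance = 1e-9)
})

test_that("no warming puts every historical cell in the refugia category", {
  g <- make_baseline(nrow = 10, ncol = 10, seed = 4)
  same <- list({f <- g; f$label <- "GxS"; f})
  sc <- assemble_scenarios(g, same)
  rg <- species_range("sp", rect_poly(115.5, -37.5, 117, -36.5),
                      rect_poly(115.5, -37.5, 116.5, -37))
  rf <- refugia_map(rg, sc)
  expect_equal(rf$area_fractions$fraction[rf$area_fractions$category == "all"], 1)

  # pushing one known cell above the TM in one of two scenarios makes it 'some'
  samp <- extract_cell_values(g, rg$historical)
  tm <- max(samp$values)
  r <- samp$cells$row[1]; cl <- samp$cells$col[1]
  hot1 <- g; hot1$values[r, cl] <- tm + 5; hot1$label <- "G1xS"
  sc2 <- assemble_scenarios(g, list(hot1, same[[1]]))
  rf2 <- refugia_map(rg, sc2, hist_envelope = compute_envelope(samp, "historical"))
  expect_identical(rf2$categories[r, cl], 2L)
  expect_equal(sum(rf2$categories == 2L), 1)
  expect_equal(sum(rf2$categories == 1L), samp$n_cells - 1)
})

test_that("refugia grids round-trip through the ASCII writer", {
  sc <- test_world()
  sp <- make_species(sc, "high", seed = 13)
  rf <- refugia_map(sp$range, sc)
  p <- withr::local_tempfile(fileext = ".asc")
  write_refugia(rf, p)
  g <- read_climate_grid(p)
  m <- g$values
  m[is.na(m)] <- -1
  expect_equal(sum(m == 1) + sum(m == 2) + sum(m == 3),
               sum(rf$categories > 0))
})
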