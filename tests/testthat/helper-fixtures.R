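# shared builders for small in-code fixtures

fixture_path <- function(name) {
  system.file("extdata", name, package = "heatrisk", mustWork = TRUE)
}

read_table2 <- function() {
  readr::read_csv(fixture_path("table2_species.csv"), show_col_types = FALSE)
}

read_table3 <- function() {
  readr::read_csv(fixture_path("table3_sites.csv"), show_col_types = FALSE)
}

# tiny deterministic grid: values filled row-major from `vals`
tiny_grid <- function(vals, nrow = 2, ncol = 2, xmin = 0, ymin = 0,
                      cellsize = 1, label = "test") {
  climate_grid(matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE),
               xmin = xmin, ymin = ymin, cellsize = cellsize, label = label)
}

# axis-aligned rectangle polygon
rect_poly <- function(x0, y0, x1, y1) {
  heat_poly(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

# random simple (star-shaped) polygon: one jittered vertex per angular
# sector, so the center is interior and the ring cannot self-intersect
random_simple_poly <- function(n = 8, cx = 0, cy = 0, rmin = 0.5, rmax = 3) {
  sector <- 2 * pi / n
  ang <- (seq_len(n) - 1) * sector + runif(n, 0, 0.9 * sector)
  r <- runif(n, rmin, rmax)
  heat_poly(cbind(cx + r * cos(ang), cy + r * sin(ang)))
}

# brute-force zonal oracle: per-cell point-in-polygon loop over cell centers
# using mgcv::in.out, fully independent of the package's ray caster
oracle_extract <- function(grid, poly) {
  cc <- cell_centers(grid, valid_only = TRUE)
  bnd <- do.call(rbind, lapply(poly$rings, function(r)
    rbind(r, r[1, ], c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  keep <- mgcv::in.out(bnd, as.matrix(cc[, c("x", "y")]))
  sort(cc$value[keep])
}

# shoelace area of a simple ring
shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# small standard scenario world shared across tests (built once per run)
test_world <- local({
  world <- NULL
  function() {
    if (is.null(world)) {
      b <- make_baseline(seed = 42)
      world <<- make_scenarios(b, seed = 42)
    }
    world
  }
})
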