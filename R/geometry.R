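#' Polygon container
#'
#' Polygons are stored as a list of rings, each ring a two-column numeric
#' matrix of vertices (x, y), not explicitly closed. Multi-part geometries
#' and holes are both expressed as additional rings under the even-odd fill
#' rule: a point is inside the polygon if a ray from it crosses the union of
#' ring boundaries an odd number of times. Self-intersecting ("bow-tie")
#' rings are valid under this rule and are interpreted — not rejected — so
#' invalid upstream geometry is repaired by reinterpretation rather than by
#' a buffering pass.
#'
#' @param rings A two-column matrix (single ring) or list of such matrices.
#' @return An object of class `heat_poly`.
#' @export
heat_poly <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  if (!is.list(rings) || length(rings) == 0L)
    stop("`rings` must be a matrix or a non-empty list of matrices", call. = FALSE)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L || !is.numeric(r) || any(!is.finite(r)))
      stop("each ring must be a finite numeric matrix with >= 3 vertices and 2 columns",
           call. = FALSE)
    # drop an explicit closing vertex
    if (all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop("ring degenerates to < 3 vertices", call. = FALSE)
    unname(r)
  })
  structure(list(rings = rings), class = "heat_poly")
}

#' @export
print.heat_poly <- function(x, ...) {
  b <- poly_bbox(x)
  cat(sprintf("<heat_poly> %d ring(s), %d vertices, area %.6g\n  bbox x [%g, %g] y [%g, %g]\n",
              length(x$rings), sum(vapply(x$rings, nrow, integer(1))),
              poly_area(x), b["xmin"], b["xmax"], b["ymin"], b["ymax"]))
  invisible(x)
}

#' @rdname heat_poly
#' @param poly A `heat_poly`.
#' @export
poly_bbox <- function(poly) {
  xs <- unlist(lapply(poly$rings, function(r) r[, 1L]))
  ys <- unlist(lapply(poly$rings, function(r) r[, 2L]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

poly_edges <- function(poly) {
  do.call(rbind, lapply(poly$rings, function(r) {
    n <- nrow(r)
    cbind(x1 = r[, 1L], y1 = r[, 2L],
          x2 = r[c(2:n, 1L), 1L], y2 = r[c(2:n, 1L), 2L])
  }))
}

#' Test points against a polygon (even-odd rule)
#'
#' Vectorised ray-casting over all rings. Points exactly on a boundary edge
#' follow the ray-casting convention (half-open edges), which is consistent
#' across calls.
#'
#' @param px,py Point coordinates (equal-length numeric vectors).
#' @param poly A [heat_poly].
#' @return Logical vector, `TRUE` where the point is inside.
#' @export
point_in_poly <- function(px, py, poly) {
  stopifnot(inherits(poly, "heat_poly"), length(px) == length(py))
  inside <- logical(length(px))
  for (ring in poly$rings) {
    x <- ring[, 1L]; y <- ring[, 2L]
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    for (i in seq_len(n)) {
      xi <- x[i]; yi <- y[i]; xj <- x[j[i]]; yj <- y[j[i]]
      if (yi == yj) next
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

# x-coordinates of proper interior crossings between segments; used to cut
# sweep strips so no two edges cross inside a strip
segment_crossings_x <- function(E) {
  n <- nrow(E)
  if (n < 2L) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(n - 1L)) {
    p <- E[i, ]
    for (j in (i + 1L):n) {
      q <- E[j, ]
      d1x <- p["x2"] - p["x1"]; d1y <- p["y2"] - p["y1"]
      d2x <- q["x2"] - q["x1"]; d2y <- q["y2"] - q["y1"]
      den <- d1x * d2y - d1y * d2x
      if (den == 0) next
      t <- ((q["x1"] - p["x1"]) * d2y - (q["y1"] - p["y1"]) * d2x) / den
      u <- ((q["x1"] - p["x1"]) * d1y - (q["y1"] - p["y1"]) * d1x) / den
      if (t > 0 && t < 1 && u > 0 && u < 1)
        out <- c(out, p["x1"] + t * d1x)
    }
  }
  unname(out)
}

#' Area of a polygon under the even-odd fill rule
#'
#' Exact trapezoid-sweep over the edge arrangement: the x-axis is cut at
#' every vertex and every edge crossing, and within each strip the filled
#' bands lie between consecutively stacked edges. Agrees with the shoelace
#' formula for simple rings and assigns self-intersecting rings the area of
#' their filled (odd-parity) region — e.g. a bow-tie gets the summed area of
#' its two triangles.
#'
#' @param poly A [heat_poly].
#' @return Non-negative area in squared coordinate units.
#' @export
poly_area <- function(poly) {
  stopifnot(inherits(poly, "heat_poly"))
  E <- poly_edges(poly)
  E <- E[E[, "x1"] != E[, "x2"], , drop = FALSE]  # verticals carry no strip area
  if (nrow(E) == 0L) return(0)
  xs <- sort(unique(c(E[, "x1"], E[, "x2"], segment_crossings_x(E))))
  total <- 0
  for (s in seq_len(length(xs) - 1L)) {
    x0 <- xs[s]; x1 <- xs[s + 1L]
    if (x1 - x0 <= 0) next
    xm <- (x0 + x1) / 2
    lo <- pmin(E[, "x1"], E[, "x2"]); hi <- pmax(E[, "x1"], E[, "x2"])
    span <- lo <= x0 + 1e-12 & hi >= x1 - 1e-12
    if (!any(span)) next
    Es <- E[span, , drop = FALSE]
    y_at <- function(xq) Es[, "y1"] +
      (Es[, "y2"] - Es[, "y1"]) * (xq - Es[, "x1"]) / (Es[, "x2"] - Es[, "x1"])
    ord <- order(y_at(xm))
    y0 <- y_at(x0)[ord]; y1v <- y_at(x1)[ord]
    m <- length(ord)
    if (m %% 2L != 0L) next  # numerically degenerate strip
    odd <- seq(1L, m, by = 2L)
    total <- total + sum(((y0[odd + 1L] - y0[odd]) +
                            (y1v[odd + 1L] - y1v[odd])) / 2) * (x1 - x0)
  }
  total
}

#' Union two polygons' parts
#'
#' Concatenates the rings of two polygons. Under the even-odd rule this is an
#' exact union only for disjoint geometries (the case produced by the range
#' constructions here); overlapping parts would cancel.
#'
#' @param a,b [heat_poly] objects with disjoint interiors.
#' @export
poly_union <- function(a, b) heat_poly(c(a$rings, b$rings))

# grid cells (row, col) whose rectangle the segment passes through
cells_on_segment <- function(x1, y1, x2, y2, grid) {
  cs <- grid$cellsize
  e <- grid_extent(grid)
  # parameter breakpoints at every x and y gridline crossed
  ts <- c(0, 1)
  if (x2 != x1) {
    gx <- grid$xmin + (0:ncol(grid$values)) * cs
    k <- (gx - x1) / (x2 - x1)
    ts <- c(ts, k[k > 0 & k < 1])
  }
  if (y2 != y1) {
    gy <- grid$ymin + (0:nrow(grid$values)) * cs
    k <- (gy - y1) / (y2 - y1)
    ts <- c(ts, k[k > 0 & k < 1])
  }
  ts <- sort(unique(ts))
  tm <- (head(ts, -1) + tail(ts, -1)) / 2
  px <- x1 + tm * (x2 - x1); py <- y1 + tm * (y2 - y1)
  col <- floor((px - grid$xmin) / cs) + 1L
  row <- floor((e["ymax"] - py) / cs) + 1L
  keep <- row >= 1L & row <= nrow(grid$values) & col >= 1L & col <= ncol(grid$values)
  unique(cbind(row = row[keep], col = col[keep]))
}

# all cells touched by the polygon boundary or containing a vertex
cells_touched_by_boundary <- function(poly, grid) {
  E <- poly_edges(poly)
  parts <- lapply(seq_len(nrow(E)), function(i)
    cells_on_segment(E[i, "x1"], E[i, "y1"], E[i, "x2"], E[i, "y2"], grid))
  unique(do.call(rbind, parts))
}

#' Build a polygon as the union of grid-cell rectangles
#'
#' Cells are merged into per-row runs of contiguous columns, each run one
#' rectangular ring, so cell-center containment tests are exact by
#' construction. Used by the synthetic range generator.
#'
#' @param cells Data frame / tibble with integer `row`, `col`.
#' @param grid The [climate_grid] defining cell geometry.
#' @return A [heat_poly].
#' @export
cells_to_poly <- function(cells, grid) {
  stopifnot(nrow(cells) >= 1L)
  e <- grid_extent(grid); cs <- grid$cellsize
  cells <- dplyr::arrange(as_tibble(cells[, c("row", "col")]), row, col)
  rings <- list()
  for (r in unique(cells$row)) {
    cc <- cells$col[cells$row == r]
    runs <- split(cc, cumsum(c(1L, diff(cc) != 1L)))
    for (run in runs) {
      x0 <- grid$xmin + (min(run) - 1L) * cs
      x1 <- grid$xmin + max(run) * cs
      y1 <- e["ymax"] - (r - 1L) * cs
      y0 <- e["ymax"] - r * cs
      rings[[length(rings) + 1L]] <-
        cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
    }
  }
  heat_poly(rings)
}
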