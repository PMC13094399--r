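#' Gridded BIO5 climate layer
#'
#' A `climate_grid` holds one gridded layer of BIO5 (maximum temperature of
#' the warmest month, degrees C) on a regular, north-up, square-celled grid.
#' Missing cells (ocean, out-of-domain) are `NA` in `values`. Row 1 is the
#' northernmost row; cell values are referenced at cell centers and the grid
#' origin (`xmin`, `ymin`) is the lower-left corner of the extent.
#'
#' @param values Numeric matrix of BIO5 in degrees C, `NA` for nodata.
#' @param xmin,ymin Coordinates of the lower-left corner of the extent.
#' @param cellsize Cell edge length in coordinate units (square cells).
#' @param crs Coordinate reference identifier (free text, e.g. "EPSG:4326").
#' @param label Free-text label, e.g. `"baseline"` or a GCM x SSP tag.
#'
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                         crs = "EPSG:4326", label = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!any(is.finite(values)))
    stop("empty grid: no valid (non-nodata) cell", call. = FALSE)
  if (any(is.infinite(values)))
    stop("grid contains non-finite values outside the nodata mask", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cellsize = as.numeric(cellsize), crs = crs, label = label),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  e <- grid_extent(x)
  cat(sprintf(
    "<climate_grid> %s\n  %d x %d cells (%d valid), cellsize %g, %s\n  extent x [%g, %g] y [%g, %g]\n  BIO5 range [%.2f, %.2f] degC\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    nrow(x$values), ncol(x$values), sum(is.finite(x$values)), x$cellsize,
    x$crs, e["xmin"], e["xmax"], e["ymin"], e["ymax"],
    min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @rdname climate_grid
#' @param x A `climate_grid`.
#' @export
grid_extent <- function(x) {
  stopifnot(inherits(x, "climate_grid"))
  c(xmin = x$xmin, xmax = x$xmin + ncol(x$values) * x$cellsize,
    ymin = x$ymin, ymax = x$ymin + nrow(x$values) * x$cellsize)
}

#' Cell-center coordinates and values of a grid
#'
#' @param x A `climate_grid`.
#' @param valid_only Drop nodata cells? Default `TRUE`.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`, in
#'   row-major order (row 1 / northernmost first).
#' @export
cell_centers <- function(x, valid_only = TRUE) {
  stopifnot(inherits(x, "climate_grid"))
  nr <- nrow(x$values); nc <- ncol(x$values)
  ymax <- x$ymin + nr * x$cellsize
  out <- tibble(
    row = rep(seq_len(nr), each = nc),
    col = rep(seq_len(nc), times = nr),
    value = as.vector(t(x$values))
  )
  out$x <- x$xmin + (out$col - 0.5) * x$cellsize
  out$y <- ymax - (out$row - 0.5) * x$cellsize
  out <- out[, c("row", "col", "x", "y", "value")]
  if (valid_only) out <- out[is.finite(out$value), ]
  out
}

grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

#' Read a gridded BIO5 layer from an ESRI ASCII grid file
#'
#' Reads the standard text raster interchange format (`.asc`: a six-line
#' header of `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`, then rows of values north to south). Datasets that store
#' temperature as scaled integers (e.g. degC x 10) are handled through
#' `scale`/`offset`: stored values are transformed as `value * scale + offset`.
#'
#' @param path Path to an ASCII grid file.
#' @param label Label attached to the returned grid.
#' @param scale,offset Linear transform applied to stored values (defaults
#'   leave values unchanged).
#' @param crs Coordinate reference identifier to record.
#' @return A [climate_grid].
#' @export
read_climate_grid <- function(path, label = "", scale = 1, offset = 0,
                              crs = "EPSG:4326") {
  if (!file.exists(path)) stop("cannot read grid: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed ASCII grid header in ", path, call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  m <- m * scale + offset
  if (!any(is.finite(m)))
    stop("empty grid: every cell is nodata in ", path, call. = FALSE)
  climate_grid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
               cellsize = hdr$cellsize, crs = crs, label = label)
}

#' Write a climate grid to an ESRI ASCII grid file
#'
#' @param x A [climate_grid].
#' @param path Output path.
#' @param nodata Sentinel written for `NA` cells.
#' @param digits Significant digits used for values (default 15 keeps
#'   round-trips exact for double-precision climatologies).
#' @return `path`, invisibly.
#' @export
write_climate_grid <- function(x, path, nodata = -9999, digits = 15) {
  stopifnot(inherits(x, "climate_grid"))
  m <- x$values
  if (any(is.finite(m) & m == nodata))
    stop("nodata sentinel ", nodata, " collides with a real value", call. = FALSE)
  m[!is.finite(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", x$xmin),
    sprintf("yllcorner %.10g", x$ymin),
    sprintf("cellsize %.10g", x$cellsize),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble a baseline + future ensemble into a scenario set
#'
#' Verifies that every layer shares the baseline's shape, origin, cell size
#' and CRS (mismatches are an error: no silent resampling), then intersects
#' the nodata masks so a cell is either valid in every layer or excluded
#' everywhere. Future layers carry `gcm`/`ssp` labels.
#'
#' @param baseline A [climate_grid] for the baseline climatology.
#' @param futures List of [climate_grid]s, one per future scenario.
#' @param gcm,ssp Character vectors labelling each future (recycled from the
#'   grids' `label` fields if omitted).
#' @return An object of class `scenario_set` with elements `baseline`,
#'   `futures` (list of grids) and `labels` (tibble `scenario`, `gcm`, `ssp`).
#' @export
assemble_scenarios <- function(baseline, futures, gcm = NULL, ssp = NULL) {
  if (inherits(baseline, "scenario_set") && missing(futures)) return(baseline)
  stopifnot(inherits(baseline, "climate_grid"))
  if (inherits(futures, "climate_grid")) futures <- list(futures)
  if (length(futures) < 1L) stop("need at least one future grid", call. = FALSE)
  ok <- vapply(futures, grids_aligned, logical(1), b = baseline)
  if (!all(ok))
    stop("alignment error: future grid(s) ",
         paste(which(!ok), collapse = ", "),
         " do not share the baseline's shape/origin/cellsize/crs",
         call. = FALSE)
  mask <- is.finite(baseline$values)
  for (f in futures) mask <- mask & is.finite(f$values)
  if (!any(mask)) stop("empty grid: no cell valid in every layer", call. = FALSE)
  apply_mask <- function(g) { g$values[!mask] <- NA_real_; g }
  baseline <- apply_mask(baseline)
  futures <- lapply(futures, apply_mask)
  k <- length(futures)
  labs <- vapply(futures, function(f) f$label, character(1))
  labels <- tibble(
    scenario = seq_len(k),
    gcm = gcm %||% sub("[x*].*$", "", labs),
    ssp = ssp %||% sub("^.*[x*]", "", labs)
  )
  structure(list(baseline = baseline, futures = futures, labels = labels),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> baseline + %d future scenarios\n",
              length(x$futures)))
  print(x$baseline)
  invisible(x)
}

#' Number of future scenarios in a scenario set
#' @param x A `scenario_set`.
#' @export
n_scenarios <- function(x) {
  stopifnot(inherits(x, "scenario_set"))
  length(x$futures)
}
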