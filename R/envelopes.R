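#' Extract BIO5 cell values over a range polygon
#'
#' Zonal extraction: returns the values of valid grid cells included by the
#' polygon, in deterministic row-major order. The default inclusion rule
#' (`"center"`) includes a cell iff its center lies inside the polygon under
#' the even-odd rule — the standard unbiased zonal convention. For very
#' small ranges that miss every cell center, `"all_touched"` includes every
#' cell whose rectangle the polygon boundary passes through or whose center
#' is inside.
#'
#' @param grid A [climate_grid].
#' @param polygon A [heat_poly].
#' @param inclusion_rule `"center"` (default) or `"all_touched"`.
#' @param area_weighting If `TRUE`, cells are weighted by `cos(latitude)`
#'   (geographic grids), approximating equal-area weighting; otherwise
#'   uniform weights. Envelope extrema are weight-invariant; only overlap
#'   proportions respond to weights.
#' @return An object of class `value_sample`: list with `values` (degC),
#'   `weights`, `cells` (tibble `row`, `col`, `x`, `y`), `n_cells`.
#' @export
extract_cell_values <- function(grid, polygon,
                                inclusion_rule = c("center", "all_touched"),
                                area_weighting = FALSE) {
  stopifnot(inherits(grid, "climate_grid"), inherits(polygon, "heat_poly"))
  inclusion_rule <- match.arg(inclusion_rule)
  cc <- cell_centers(grid, valid_only = TRUE)
  bb <- poly_bbox(polygon)
  cand <- cc[cc$x >= bb["xmin"] - grid$cellsize & cc$x <= bb["xmax"] + grid$cellsize &
             cc$y >= bb["ymin"] - grid$cellsize & cc$y <= bb["ymax"] + grid$cellsize, ]
  inc <- cand[point_in_poly(cand$x, cand$y, polygon), ]
  if (inclusion_rule == "all_touched") {
    touched <- cells_touched_by_boundary(polygon, grid)
    key_t <- paste(touched[, "row"], touched[, "col"])
    extra <- cc[paste(cc$row, cc$col) %in% setdiff(key_t, paste(inc$row, inc$col)), ]
    inc <- dplyr::bind_rows(inc, extra)
  }
  inc <- dplyr::arrange(inc, row, col)
  if (nrow(inc) == 0L)
    stop("empty extraction: polygon includes no valid cell",
         " (consider inclusion_rule = \"all_touched\")", call. = FALSE)
  w <- if (area_weighting) cos(inc$y * pi / 180) else rep(1, nrow(inc))
  if (any(w <= 0)) stop("non-positive area weights (|latitude| >= 90?)", call. = FALSE)
  value_sample(inc$value, weights = w,
               cells = inc[, c("row", "col", "x", "y")])
}

#' Construct a value sample directly
#'
#' @param values Numeric vector of BIO5 values (degC), all finite.
#' @param weights Positive per-cell weights (default uniform).
#' @param cells Optional tibble of cell metadata.
#' @export
value_sample <- function(values, weights = NULL, cells = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("`values` must be a non-empty finite numeric vector", call. = FALSE)
  weights <- if (is.null(weights)) rep(1, length(values)) else as.numeric(weights)
  if (length(weights) != length(values) || any(!is.finite(weights)) || any(weights <= 0))
    stop("`weights` must be positive and match `values` in length", call. = FALSE)
  structure(list(values = values, weights = weights,
                 cells = cells, n_cells = length(values)),
            class = "value_sample")
}

#' @export
print.value_sample <- function(x, ...) {
  cat(sprintf("<value_sample> %d cells, BIO5 [%.2f, %.2f] degC\n",
              x$n_cells, min(x$values), max(x$values)))
  invisible(x)
}

#' Heat envelope of a value sample
#'
#' The heat envelope is the observed range `[min, max]` of BIO5 across a
#' species' range cells; its upper bound is the thermal maximum (TM). No
#' trimming or quantiles are applied: the envelope is the attained range.
#'
#' @param sample A [value_sample].
#' @param epoch `"historical"` or `"current"`.
#' @return An object of class `heat_envelope` with fields `env_min`,
#'   `env_max` (= TM), `width`, `epoch`, `n_cells`, `sample`.
#' @export
compute_envelope <- function(sample, epoch = c("current", "historical")) {
  stopifnot(inherits(sample, "value_sample"))
  epoch <- match.arg(epoch)
  env_min <- min(sample$values)
  env_max <- max(sample$values)
  structure(list(env_min = env_min, env_max = env_max,
                 width = env_max - env_min, epoch = epoch,
                 n_cells = sample$n_cells, sample = sample),
            class = "heat_envelope")
}

#' @export
print.heat_envelope <- function(x, ...) {
  cat(sprintf("<heat_envelope> %s: [%.2f, %.2f] degC (width %.2f, TM %.2f, %d cells)\n",
              x$epoch, x$env_min, x$env_max, x$width, x$env_max, x$n_cells))
  invisible(x)
}

#' Difference between historical and current thermal maxima
#'
#' `delta = historical TM - current TM`: near zero when a species still
#' occupies the hottest parts of its historical range, large when it has
#' retreated to cooler remnants.
#'
#' @param hist,curr [heat_envelope]s with epochs `"historical"` and
#'   `"current"` respectively.
#' @return The delta in degC.
#' @export
thermal_max_delta <- function(hist, curr) {
  stopifnot(inherits(hist, "heat_envelope"), inherits(curr, "heat_envelope"))
  if (hist$epoch != "historical" || curr$epoch != "current")
    stop("expected a historical and a current envelope, in that order",
         call. = FALSE)
  hist$env_max - curr$env_max
}

#' Envelope summaries for a set of species
#'
#' Convenience wrapper: extracts baseline values over both epochs' polygons
#' for each species and tabulates envelope bounds, widths and the
#' historical-minus-current thermal maximum difference.
#'
#' @param ranges List of [species_range]s.
#' @param baseline A [climate_grid] for the baseline climatology.
#' @inheritParams extract_cell_values
#' @return A tibble, one row per species.
#' @export
envelope_table <- function(ranges, baseline,
                           inclusion_rule = "center", area_weighting = FALSE) {
  purrr::map(ranges, function(rg) {
    eh <- compute_envelope(
      extract_cell_values(baseline, rg$historical, inclusion_rule, area_weighting),
      "historical")
    ec <- compute_envelope(
      extract_cell_values(baseline, rg$current, inclusion_rule, area_weighting),
      "current")
    tibble(species_id = rg$species_id,
           hist_min = eh$env_min, hist_tm = eh$env_max, hist_width = eh$width,
           curr_min = ec$env_min, curr_tm = ec$env_max, curr_width = ec$width,
           delta_tm = thermal_max_delta(eh, ec),
           n_cells_hist = eh$n_cells, n_cells_curr = ec$n_cells)
  }) |> purrr::list_rbind()
}
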