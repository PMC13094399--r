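#' Sample a grid at a point location
#'
#' Returns the value of the cell containing the point (nearest-cell rule, no
#' interpolation), matching the treatment of translocation sites as point
#' locations.
#'
#' @param grid A [climate_grid].
#' @param lon,lat Point coordinates in the grid's CRS.
#' @param site_name Optional name used in error messages.
#' @return The cell's BIO5 value in degC.
#' @export
sample_point <- function(grid, lon, lat, site_name = NULL) {
  stopifnot(inherits(grid, "climate_grid"))
  e <- grid_extent(grid)
  who <- if (is.null(site_name)) sprintf("(%g, %g)", lon, lat) else site_name
  if (lon < e["xmin"] || lon > e["xmax"] || lat < e["ymin"] || lat > e["ymax"])
    stop("site ", who, " falls outside the grid extent", call. = FALSE)
  col <- min(ncol(grid$values), floor((lon - grid$xmin) / grid$cellsize) + 1L)
  row <- min(nrow(grid$values), floor((e["ymax"] - lat) / grid$cellsize) + 1L)
  v <- grid$values[row, col]
  if (!is.finite(v))
    stop("site ", who, " falls on a nodata cell", call. = FALSE)
  v
}

#' Assess a translocation site against a species' thermal maxima
#'
#' Samples baseline and every future scenario at the site, derives the
#' mildest (per-site ensemble minimum), mean and most extreme (maximum)
#' projected BIO5, and flags strict exceedance of the current and historical
#' thermal maxima under each. Equality to a TM counts as within, since the
#' TM is itself an attained envelope value.
#'
#' @param site One-row data frame / list with `species_id`, `site_name`,
#'   `lon`, `lat`.
#' @param scenarios A `scenario_set`.
#' @param env_current,env_historical The species' baseline [heat_envelope]s.
#' @return A one-row tibble (class `site_assessment` rows): identity
#'   columns, `bio5_baseline`, `bio5_mild`, `bio5_mean`, `bio5_extreme`, a
#'   `bio5_by_scenario` list column, and six exceedance flags
#'   `above_current_{mild,mean,extreme}` / `above_historical_{...}`.
#' @export
assess_site <- function(site, scenarios, env_current, env_historical) {
  stopifnot(inherits(scenarios, "scenario_set"),
            inherits(env_current, "heat_envelope"),
            inherits(env_historical, "heat_envelope"))
  if (env_current$epoch != "current" || env_historical$epoch != "historical")
    stop("envelopes must be current and historical, in that order", call. = FALSE)
  base_v <- sample_point(scenarios$baseline, site$lon, site$lat, site$site_name)
  fut_v <- vapply(scenarios$futures, sample_point, numeric(1),
                  lon = site$lon, lat = site$lat, site_name = site$site_name)
  tm_c <- env_current$env_max
  tm_h <- env_historical$env_max
  mild <- min(fut_v); mn <- mean(fut_v); ext <- max(fut_v)
  tibble(
    species_id = site$species_id, site_name = site$site_name,
    lon = site$lon, lat = site$lat,
    bio5_baseline = base_v,
    bio5_mild = mild, bio5_mean = mn, bio5_extreme = ext,
    bio5_by_scenario = list(fut_v),
    above_current_mild = mild > tm_c,
    above_current_mean = mn > tm_c,
    above_current_extreme = ext > tm_c,
    above_historical_mild = mild > tm_h,
    above_historical_mean = mn > tm_h,
    above_historical_extreme = ext > tm_h
  )
}

#' Assess all sites of a species table
#'
#' @param sites Tibble of site records (`species_id`, `site_name`, `lon`,
#'   `lat`); all rows must belong to species present in `envelopes`.
#' @param scenarios A `scenario_set`.
#' @param envelopes Named list: per species id, a list with elements
#'   `current` and `historical` [heat_envelope]s.
#' @return Row-bound [assess_site()] tibble.
#' @export
assess_sites <- function(sites, scenarios, envelopes) {
  purrr::map(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    ev <- envelopes[[s$species_id]]
    if (is.null(ev))
      stop("no envelopes supplied for species ", s$species_id, call. = FALSE)
    assess_site(s, scenarios, ev$current, ev$historical)
  }) |> purrr::list_rbind()
}

#' Per-species summary of translocation-site exceedance
#'
#' Percentage of a species' sites whose projected BIO5 surpasses the
#' current / historical thermal maximum under the mean, mildest and most
#' extreme future scenarios.
#'
#' @param assessments Tibble from [assess_site()]/[assess_sites()] (may
#'   cover several species).
#' @return A tibble, one row per species: `n_sites` and six percentage
#'   columns `pct_above_current_{mean,mild,extreme}`,
#'   `pct_above_historical_{mean,mild,extreme}`.
#' @export
summarise_species_sites <- function(assessments) {
  stopifnot(nrow(assessments) >= 1L)
  assessments |>
    dplyr::group_by(species_id) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      pct_above_current_mean = 100 * mean(above_current_mean),
      pct_above_current_mild = 100 * mean(above_current_mild),
      pct_above_current_extreme = 100 * mean(above_current_extreme),
      pct_above_historical_mean = 100 * mean(above_historical_mean),
      pct_above_historical_mild = 100 * mean(above_historical_mild),
      pct_above_historical_extreme = 100 * mean(above_historical_extreme),
      .groups = "drop"
    )
}
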