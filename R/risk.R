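#' Percentage of a future sample remaining within a heat envelope
#'
#' The overlap statistic of the screening framework: the (weighted) share of
#' a species' current-range cells whose projected BIO5 stays within a
#' baseline heat envelope. The default mode `"upper"` tests only the hot
#' tail (`value <= env_max`): a cell "remains within" the envelope iff its
#' future BIO5 does not exceed the envelope's thermal maximum, since cooling
#' below `env_min` is not a heat risk. `"two_sided"` additionally requires
#' `value >= env_min`.
#'
#' @param future_sample A [value_sample] of projected BIO5 values.
#' @param envelope A [heat_envelope].
#' @param mode `"upper"` (default) or `"two_sided"`.
#' @return A percentage in `[0, 100]`.
#' @export
overlap_percent <- function(future_sample, envelope,
                            mode = c("upper", "two_sided")) {
  stopifnot(inherits(future_sample, "value_sample"),
            inherits(envelope, "heat_envelope"))
  mode <- match.arg(mode)
  v <- future_sample$values
  w <- future_sample$weights
  within <- if (mode == "upper") v <= envelope$env_max
            else v >= envelope$env_min & v <= envelope$env_max
  100 * sum(w[within]) / sum(w)
}

ensemble_se <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-scenario overlap of future conditions with baseline envelopes
#'
#' For each future scenario, extracts projected BIO5 over the species'
#' CURRENT range polygon and scores it against the current-epoch and
#' historical-epoch baseline envelopes, then aggregates the ensemble mean
#' and standard error (sample SD across the k scenario values / sqrt(k)).
#'
#' @param range A [species_range].
#' @param scenarios A `scenario_set` (see [assemble_scenarios]).
#' @inheritParams overlap_percent
#' @inheritParams extract_cell_values
#' @return An object of class `overlap_summary`: list with `species_id`,
#'   `per_scenario` (tibble: `scenario`, `gcm`, `ssp`, `pct_current`,
#'   `pct_historical`), ensemble `mean_current`/`se_current`/
#'   `mean_historical`/`se_historical`, the two baseline envelopes, and the
#'   `mode` used.
#' @export
summarise_overlaps <- function(range, scenarios, mode = c("upper", "two_sided"),
                               inclusion_rule = "center", area_weighting = FALSE) {
  stopifnot(inherits(range, "species_range"), inherits(scenarios, "scenario_set"))
  mode <- match.arg(mode)
  base <- scenarios$baseline
  samp_curr <- extract_cell_values(base, range$current, inclusion_rule, area_weighting)
  samp_hist <- extract_cell_values(base, range$historical, inclusion_rule, area_weighting)
  env_curr <- compute_envelope(samp_curr, "current")
  env_hist <- compute_envelope(samp_hist, "historical")
  idx <- cbind(samp_curr$cells$row, samp_curr$cells$col)
  per <- purrr::imap(scenarios$futures, function(f, i) {
    fut <- value_sample(f$values[idx], weights = samp_curr$weights,
                        cells = samp_curr$cells)
    tibble(scenario = i,
           pct_current = overlap_percent(fut, env_curr, mode),
           pct_historical = overlap_percent(fut, env_hist, mode))
  }) |> purrr::list_rbind()
  per <- dplyr::left_join(scenarios$labels, per, by = "scenario")
  structure(list(
    species_id = range$species_id,
    per_scenario = per,
    mean_current = mean(per$pct_current),
    se_current = ensemble_se(per$pct_current),
    mean_historical = mean(per$pct_historical),
    se_historical = ensemble_se(per$pct_historical),
    env_current = env_curr, env_historical = env_hist,
    mode = mode
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "<overlap_summary> %s (%d scenarios, mode %s)\n  vs current envelope:    %.1f%% (SE %.2f)\n  vs historical envelope: %.1f%% (SE %.2f)\n",
    x$species_id, nrow(x$per_scenario), x$mode,
    x$mean_current, x$se_current, x$mean_historical, x$se_historical))
  invisible(x)
}

risk_tier_rule <- function(m_current, m_historical, threshold) {
  if (m_current > threshold && m_historical > threshold) "low"
  else if (m_historical > threshold) "moderate"
  else "high"
}

#' Risk tier levels, in increasing order of concern
#'
#' @format Character vector `c("low", "moderate", "high")`, the level set
#'   (and ordering) of the `tier` factor returned by [classify_risk()].
#' @export
risk_levels <- c("low", "moderate", "high")

#' Classify heat risk from ensemble overlap statistics
#'
#' Three-tier rule on the ensemble mean overlaps at a threshold (default
#' 50%): low risk if both the current- and historical-envelope overlaps
#' exceed the threshold; moderate if only the historical overlap does; high
#' otherwise. Ties at exactly the threshold fail the criterion (the rule is
#' a strict `>`). The conservative upgrade subtracts one ensemble standard
#' error from each mean before applying the rule, so a species whose
#' `mean - SE` crosses the criterion is assigned the higher tier; a mean
#' below threshold is never downgraded.
#'
#' @param overlap An [summarise_overlaps()] result, or a list of them.
#' @param threshold Overlap threshold in percent (default 50).
#' @return A tibble with one row per species: `species_id`, the four
#'   ensemble statistics, `tier` (ordered factor low < moderate < high),
#'   `upgraded` (did the SE rule raise the tier over the raw-means tier?)
#'   and `threshold`.
#' @export
classify_risk <- function(overlap, threshold = 50) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 100)
  if (inherits(overlap, "overlap_summary")) overlap <- list(overlap)
  purrr::map(overlap, function(o) {
    stopifnot(inherits(o, "overlap_summary"))
    raw <- risk_tier_rule(o$mean_current, o$mean_historical, threshold)
    adj <- risk_tier_rule(o$mean_current - o$se_current,
                          o$mean_historical - o$se_historical, threshold)
    tibble(species_id = o$species_id,
           mean_current = o$mean_current, se_current = o$se_current,
           mean_historical = o$mean_historical, se_historical = o$se_historical,
           tier = factor(adj, levels = risk_levels, ordered = TRUE),
           upgraded = !identical(raw, adj),
           threshold = threshold)
  }) |> purrr::list_rbind()
}

#' Map thermal refugia within a species' historical range
#'
#' Benchmarks every historical-range cell against the historical thermal
#' maximum: cells whose projected BIO5 stays at or below the TM under all,
#' some, or no future scenarios are categorised accordingly; cells outside
#' the polygon are `outside`. The `all` category is the candidate refugia.
#'
#' @param range A [species_range].
#' @param scenarios A `scenario_set`.
#' @param hist_envelope The species' historical [heat_envelope]; if `NULL`
#'   it is computed from the scenario baseline. A current-epoch envelope may
#'   be passed to benchmark against the current TM instead.
#' @inheritParams extract_cell_values
#' @return An object of class `refugia_map`: `categories` (integer matrix,
#'   codes 0 outside / 1 all / 2 some / 3 none), `area_fractions` (tibble
#'   over all/some/none, summing to 1), `benchmark_tm`, and grid geometry.
#' @export
refugia_map <- function(range, scenarios, hist_envelope = NULL,
                        inclusion_rule = "center", area_weighting = FALSE) {
  stopifnot(inherits(range, "species_range"), inherits(scenarios, "scenario_set"))
  base <- scenarios$baseline
  samp <- extract_cell_values(base, range$historical, inclusion_rule, area_weighting)
  env <- hist_envelope %||%
    compute_envelope(samp, "historical")
  stopifnot(inherits(env, "heat_envelope"))
  tm <- env$env_max
  idx <- cbind(samp$cells$row, samp$cells$col)
  k <- n_scenarios(scenarios)
  below <- rep(0L, nrow(idx))
  for (f in scenarios$futures) below <- below + (f$values[idx] <= tm)
  cat_codes <- ifelse(below == k, 1L, ifelse(below > 0L, 2L, 3L))
  categories <- matrix(0L, nrow(base$values), ncol(base$values))
  categories[idx] <- cat_codes
  w <- samp$weights
  fr <- vapply(1:3, function(code) sum(w[cat_codes == code]) / sum(w), numeric(1))
  structure(list(
    species_id = range$species_id,
    categories = categories,
    area_fractions = tibble(category = c("all", "some", "none"), fraction = fr),
    benchmark_tm = tm, benchmark_epoch = env$epoch,
    xmin = base$xmin, ymin = base$ymin, cellsize = base$cellsize,
    crs = base$crs
  ), class = "refugia_map")
}

#' @export
print.refugia_map <- function(x, ...) {
  cat(sprintf("<refugia_map> %s (benchmark %s TM %.2f degC)\n",
              x$species_id, x$benchmark_epoch, x$benchmark_tm))
  fr <- x$area_fractions
  cat(sprintf("  below TM under %-4s scenarios: %5.1f%%\n",
              fr$category, 100 * fr$fraction), sep = "")
  invisible(x)
}

#' Write a refugia category map as an ASCII grid
#'
#' Integer codes: 0 outside the historical range, 1 below the TM under all
#' scenarios (refugia), 2 under some, 3 under none.
#'
#' @param x A [refugia_map].
#' @param path Output path.
#' @export
write_refugia <- function(x, path) {
  stopifnot(inherits(x, "refugia_map"))
  g <- climate_grid(x$categories + 0, xmin = x$xmin, ymin = x$ymin,
                    cellsize = x$cellsize, crs = x$crs,
                    label = paste0("refugia:", x$species_id))
  write_climate_grid(g, path, nodata = -1, digits = 1)
  invisible(path)
}
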