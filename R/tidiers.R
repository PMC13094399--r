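#' Tidy a hypothesis-test result
#'
#' @param x A `heat_test`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @exportS3Method generics::tidy
tidy.heat_test <- function(x, ...) {
  tibble(statistic = x$statistic,
         df = if (is.null(x$df)) NA_real_ else as.numeric(x$df),
         p_value = x$p_value, method = x$method)
}

#' @rdname tidy.heat_test
#' @exportS3Method generics::glance
glance.heat_test <- function(x, ...) tidy(x)

#' Tidy per-scenario overlaps
#'
#' @param x An `overlap_summary`.
#' @param ... Unused.
#' @return Tibble with one row per future scenario.
#' @exportS3Method generics::tidy
tidy.overlap_summary <- function(x, ...) {
  dplyr::mutate(x$per_scenario, species_id = x$species_id, .before = 1)
}

#' @rdname tidy.overlap_summary
#' @return For `glance()`: one row of ensemble statistics.
#' @exportS3Method generics::glance
glance.overlap_summary <- function(x, ...) {
  tibble(species_id = x$species_id,
         mean_current = x$mean_current, se_current = x$se_current,
         mean_historical = x$mean_historical, se_historical = x$se_historical,
         n_scenarios = nrow(x$per_scenario), mode = x$mode)
}

#' Tidy a refugia map into long cell / fraction form
#'
#' @param x A `refugia_map`.
#' @param ... Unused.
#' @return The area-fraction tibble with the species id attached.
#' @exportS3Method generics::tidy
tidy.refugia_map <- function(x, ...) {
  dplyr::mutate(x$area_fractions, species_id = x$species_id, .before = 1)
}

#' Tidy a risk crosstab
#'
#' @param x A `risk_crosstab`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.risk_crosstab <- function(x, ...) x$table

#' Tidy a heat envelope
#'
#' @param x A `heat_envelope`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.heat_envelope <- function(x, ...) {
  tibble(epoch = x$epoch, env_min = x$env_min, env_max = x$env_max,
         width = x$width, thermal_max = x$env_max, n_cells = x$n_cells)
}
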