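risk_palette <- c(low = "#2c7fb8", moderate = "#fe9929", high = "#d7301f")

#' Risk scatter of ensemble overlaps
#'
#' Mean overlap with the historical envelope against mean overlap with the
#' current envelope, one point per species with ensemble-SE error bars;
#' the threshold lines partition the plane into the three risk tiers
#' (lower-left quadrant = high risk).
#'
#' @param risk A [classify_risk()] tibble.
#' @param threshold Threshold percent drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_risk_scatter <- function(risk, threshold = 50) {
  ggplot2::ggplot(risk, ggplot2::aes(x = mean_current, y = mean_historical,
                                     colour = tier)) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_historical - se_historical,
                                        ymax = mean_historical + se_historical),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = mean_current - se_current,
                                         xmax = mean_current + se_current),
                            height = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = risk_palette) +
    ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "future overlap with current envelope (%)",
                  y = "future overlap with historical envelope (%)",
                  colour = "risk tier") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.refugia_map <- function(object, ...) {
  cats <- object$categories
  nr <- nrow(cats); nc <- ncol(cats)
  ymax <- object$ymin + nr * object$cellsize
  d <- tibble(
    x = rep(object$xmin + (seq_len(nc) - 0.5) * object$cellsize, each = nr),
    y = rep(ymax - (seq_len(nr) - 0.5) * object$cellsize, times = nc),
    code = as.vector(cats)
  )
  d <- d[d$code > 0L, ]
  d$category <- factor(c("all", "some", "none")[d$code],
                       levels = c("all", "some", "none"))
  ggplot2::ggplot(d, ggplot2::aes(x, y, fill = category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(all = "#1a9850", some = "#fe9929", none = "#d7301f"),
      name = "below historical TM under") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Thermal refugia: ", object$species_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.overlap_summary <- function(object, ...) {
  per <- tidyr::pivot_longer(object$per_scenario,
                             c(pct_current, pct_historical),
                             names_to = "benchmark", values_to = "pct")
  per$benchmark <- sub("^pct_", "", per$benchmark)
  ggplot2::ggplot(per, ggplot2::aes(benchmark, pct)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 50, linetype = 2, colour = "grey40") +
    ggplot2::labs(title = object$species_id,
                  y = "overlap of future values with envelope (%)",
                  x = "baseline envelope") +
    ggplot2::theme_minimal()
}

#' Heat exposure profile of a species
#'
#' Density curves of baseline BIO5 over the historical and current ranges
#' with the mildest and most extreme projected futures over the current
#' range, and the historical thermal maximum as a reference line.
#'
#' @param range A [species_range].
#' @param scenarios A `scenario_set`.
#' @param bandwidth Passed to [export_density_profile()].
#' @return A ggplot object.
#' @export
plot_heat_profile <- function(range, scenarios, bandwidth = NULL) {
  base <- scenarios$baseline
  sh <- extract_cell_values(base, range$historical)
  sc <- extract_cell_values(base, range$current)
  idx <- cbind(sc$cells$row, sc$cells$col)
  fut <- vapply(scenarios$futures, function(f) mean(f$values[idx]), numeric(1))
  mild <- scenarios$futures[[which.min(fut)]]
  extreme <- scenarios$futures[[which.max(fut)]]
  curves <- dplyr::bind_rows(
    dplyr::mutate(export_density_profile(sh, bandwidth), layer = "historical"),
    dplyr::mutate(export_density_profile(sc, bandwidth), layer = "current"),
    dplyr::mutate(export_density_profile(
      value_sample(mild$values[idx], sc$weights), bandwidth), layer = "future (mild)"),
    dplyr::mutate(export_density_profile(
      value_sample(extreme$values[idx], sc$weights), bandwidth),
      layer = "future (extreme)"))
  tm_h <- max(sh$values)
  ggplot2::ggplot(curves, ggplot2::aes(temperature, density, colour = layer)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = tm_h, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(
      historical = "#08306b", current = "#6baed6",
      `future (mild)` = "#fe9929", `future (extreme)` = "#d7301f")) +
    ggplot2::labs(title = range$species_id, x = "BIO5 (degC)", y = "density") +
    ggplot2::theme_minimal()
}

#' Translocation-site exposure plot
#'
#' Per site: projected ensemble-mean BIO5 with a bar spanning the mildest
#' to most extreme scenario, against the species' current and historical
#' thermal maxima.
#'
#' @param assessments An [assess_sites()] tibble for one species.
#' @param env_current,env_historical The species' [heat_envelope]s.
#' @return A ggplot object.
#' @export
plot_sites <- function(assessments, env_current, env_historical) {
  ggplot2::ggplot(assessments, ggplot2::aes(site_name, bio5_mean)) +
    ggplot2::geom_hline(yintercept = env_historical$env_max,
                        colour = "#d7301f", linetype = 2) +
    ggplot2::geom_hline(yintercept = env_current$env_max,
                        colour = "black", linetype = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = bio5_mild, ymax = bio5_extreme),
                           width = 0.2, colour = "#fe9929") +
    ggplot2::geom_point(colour = "#08519c", size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = bio5_baseline), shape = 5,
                        colour = "#08519c") +
    ggplot2::labs(x = NULL, y = "BIO5 (degC)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
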