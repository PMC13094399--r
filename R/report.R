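#' Kernel-density export of a BIO5 sample
#'
#' Gaussian KDE of a value sample, evaluated on a fixed grid and
#' renormalised so the trapezoid integral is 1 (within 1e-3). Used for heat
#' exposure profile plots; never used in classification, which operates on
#' the attained envelope only.
#'
#' @param sample A [value_sample].
#' @param bandwidth Kernel SD in degC (`NULL` = Silverman's rule; singleton
#'   samples fall back to 0.5 degC).
#' @param n Number of evaluation points.
#' @return A tibble with columns `temperature`, `density`.
#' @export
export_density_profile <- function(sample, bandwidth = NULL, n = 512) {
  stopifnot(inherits(sample, "value_sample"))
  v <- sample$values
  w <- sample$weights / sum(sample$weights)
  bw <- bandwidth %||% if (length(v) > 1L && stats::sd(v) > 0)
    stats::bw.nrd0(v) else 0.5
  d <- stats::density(v, bw = bw, weights = w, n = n,
                      from = min(v) - 4 * bw, to = max(v) + 4 * bw)
  area <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  tibble(temperature = d$x, density = d$y / area)
}

default_config <- function() {
  list(mode = "upper", threshold = 50, inclusion_rule = "center",
       area_weighting = FALSE, dunn_adjustment = "none",
       grid_scale = 1, grid_offset = 0, seed = 1)
}

#' Load a run configuration
#'
#' @param path Path to a YAML configuration file; see [run_screening()] for
#'   recognised fields.
#' @return Config list with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Run the full heat-risk screening pipeline
#'
#' Orchestrates the framework end to end from a configuration: reads the
#' baseline and future grids, range polygons and optional sites / traits /
#' study-count tables; computes per-species envelopes, ensemble overlaps,
#' risk tiers and refugia maps; assesses translocation sites; runs the
#' trait association tests; and writes all outputs as machine-readable
#' artifacts into `out_dir`. Any stage failure aborts with a stage-named
#' error and removes partial outputs.
#'
#' Config fields: `baseline` (path to ASCII grid), `futures` (list of
#' `{path, gcm, ssp}`), `ranges` (GeoJSON path), optional `sites`, `traits`,
#' `studies` (CSV paths), `out_dir`, plus the analysis knobs `mode`
#' (`upper`/`two_sided`), `threshold` (percent), `inclusion_rule`,
#' `area_weighting`, `dunn_adjustment`, `grid_scale`, `grid_offset`, `seed`.
#'
#' @param config A config list or path to a YAML file ([read_config()]).
#' @return Invisibly, a list with the main result tables (`envelopes`,
#'   `risk`, `overlaps_by_scenario`, `site_assessments`, `site_summary`,
#'   `refugia_fractions`, `tests`) and `out_dir`.
#' @export
run_screening <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_config(), config)
  for (f in c("baseline", "futures", "ranges", "out_dir"))
    if (is.null(config[[f]]))
      stop("config error: missing required field `", f, "`", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit_csv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    set.seed(config$seed)

    stage <- "read grids"
    baseline <- read_climate_grid(config$baseline, label = "baseline",
                                  scale = config$grid_scale,
                                  offset = config$grid_offset)
    futs <- purrr::map(config$futures, function(f)
      read_climate_grid(f$path, label = paste0(f$gcm, "x", f$ssp),
                        scale = config$grid_scale, offset = config$grid_offset))
    scenarios <- assemble_scenarios(
      baseline, futs,
      gcm = purrr::map_chr(config$futures, "gcm"),
      ssp = purrr::map_chr(config$futures, "ssp"))

    stage <- "read ranges"
    ranges <- read_ranges(config$ranges)
    if (length(ranges) == 0L) stop("no usable species ranges", call. = FALSE)

    stage <- "envelopes"
    env_tab <- envelope_table(ranges, scenarios$baseline,
                              inclusion_rule = config$inclusion_rule,
                              area_weighting = config$area_weighting)
    emit_csv(env_tab, "envelopes.csv")

    stage <- "overlaps and risk classification"
    overlaps <- purrr::map(ranges, summarise_overlaps, scenarios = scenarios,
                           mode = config$mode,
                           inclusion_rule = config$inclusion_rule,
                           area_weighting = config$area_weighting)
    risk <- classify_risk(overlaps, threshold = config$threshold)
    per_scen <- purrr::map(overlaps, tidy) |> purrr::list_rbind()
    emit_csv(per_scen, "overlaps_by_scenario.csv")

    stage <- "read traits"
    traits <- NULL
    if (!is.null(config$traits)) {
      traits <- readr::read_csv(config$traits, show_col_types = FALSE)
      if (!"species_id" %in% names(traits))
        stop("traits CSV must have a species_id column", call. = FALSE)
    }
    risk_out <- if (!is.null(traits))
      dplyr::left_join(risk, traits, by = "species_id") else risk
    emit_csv(risk_out, "risk.csv")

    stage <- "refugia maps"
    refugia <- purrr::map(ranges, refugia_map, scenarios = scenarios,
                          inclusion_rule = config$inclusion_rule,
                          area_weighting = config$area_weighting)
    for (rf in refugia) {
      p <- file.path(out_dir, paste0("refugia_", rf$species_id, ".asc"))
      write_refugia(rf, p)
      written <- c(written, p)
    }
    refugia_fr <- purrr::map(refugia, function(rf)
      dplyr::mutate(rf$area_fractions, species_id = rf$species_id,
                    .before = 1)) |> purrr::list_rbind()
    emit_csv(refugia_fr, "refugia_fractions.csv")

    stage <- "translocation sites"
    site_assess <- NULL; site_summary <- NULL
    if (!is.null(config$sites)) {
      sites <- read_sites(config$sites)
      envs <- purrr::map(ranges, function(rg) {
        list(current = compute_envelope(
               extract_cell_values(scenarios$baseline, rg$current,
                                   config$inclusion_rule,
                                   config$area_weighting), "current"),
             historical = compute_envelope(
               extract_cell_values(scenarios$baseline, rg$historical,
                                   config$inclusion_rule,
                                   config$area_weighting), "historical"))
      })
      site_assess <- assess_sites(sites, scenarios, envs)
      emit_csv(dplyr::select(site_assess, -bio5_by_scenario),
               "site_assessments.csv")
      site_summary <- summarise_species_sites(site_assess)
      emit_csv(site_summary, "site_summary.csv")
    }

    stage <- "trait statistics"
    tests <- list()
    if (!is.null(traits)) {
      for (tr in intersect(c("order", "iucn"), names(traits))) {
        ct <- risk_crosstab(risk, traits, tr)
        emit_csv(ct$table, paste0("crosstab_", tr, ".csv"))
        tests[[paste0("chisq_", tr)]] <-
          tidy(chi_squared_independence(ct$counts))
      }
      cont <- intersect(c("log_body_mass", "log_range_area", "delta_tm",
                          "hist_width", "curr_width", "pct_arid",
                          "pct_remnant"), names(traits))
      tdat <- dplyr::left_join(risk[, c("species_id", "tier")], traits,
                               by = "species_id")
      tdat <- dplyr::left_join(tdat,
                               env_tab[, c("species_id", "delta_tm",
                                           "hist_width", "curr_width")],
                               by = "species_id")
      for (v in intersect(c("log_body_mass", "log_range_area", "delta_tm",
                            "hist_width", "curr_width", "pct_arid",
                            "pct_remnant"), names(tdat))) {
        if (dplyr::n_distinct(tdat$tier) < 2L) break
        tests[[paste0("kw_", v)]] <- tidy(kruskal_wallis(tdat, v, "tier"))
        dn <- dunn_posthoc(tdat, v, "tier",
                           adjustment = config$dunn_adjustment)
        emit_csv(dn, paste0("dunn_", v, ".csv"))
      }
    }
    if (!is.null(config$studies)) {
      sc <- readr::read_csv(config$studies, show_col_types = FALSE)
      rt <- review_tally(sc[, c("species_id", "n_studies")], risk)
      emit_csv(rt$summary, "study_tally.csv")
      if (!is.null(rt$test)) tests[["kw_studies"]] <- tidy(rt$test)
    }
    if (length(tests))
      emit_csv(purrr::list_rbind(purrr::imap(
        tests, function(t, nm) dplyr::mutate(t, test = nm, .before = 1))),
        "association_tests.csv")

    stage <- "run manifest"
    manifest <- list(
      config = config[setdiff(names(config), "out_dir")],
      n_species = length(ranges),
      n_scenarios = n_scenarios(scenarios),
      software = list(R = paste(R.version$major, R.version$minor, sep = "."),
                      heatrisk = as.character(utils::packageVersion("heatrisk"))),
      outputs = basename(written)
    )
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, p)

    list(envelopes = env_tab, risk = risk_out, overlaps_by_scenario = per_scen,
         site_assessments = site_assess, site_summary = site_summary,
         refugia_fractions = refugia_fr,
         tests = if (length(tests)) purrr::list_rbind(tests) else NULL,
         out_dir = out_dir)
  }, error = function(e) {
    unlink(written)
    stop("screening failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a baseline + ensemble, a set of species with known tiers
#' (ground truth recorded in the returned object and in
#' `truth_species.csv`), translocation sites, a trait table and a
#' study-count table, all in the interchange formats [run_screening()]
#' consumes, plus a ready-to-run `config.yaml`.
#'
#' @param dir Output directory.
#' @param n_per_tier Species generated per risk tier.
#' @param n_sites_per_species Translocation sites per species.
#' @param seed Integer master seed (all sub-generators derive from it).
#' @param k_scenarios,spatial_pattern,noise_sd Passed to the generators.
#' @return Invisibly, list with `config` (path), `truth` (tibble of
#'   intended tiers and achieved overlaps) and `site_truth`.
#' @export
simulate_bundle <- function(dir, n_per_tier = 2, n_sites_per_species = 4,
                            seed = 1, k_scenarios = 15,
                            spatial_pattern = "uniform", noise_sd = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  baseline <- make_baseline(seed = seed, noise_sd = noise_sd)
  scenarios <- make_scenarios(baseline, k_scenarios = k_scenarios,
                              spatial_pattern = spatial_pattern, seed = seed)
  write_climate_grid(scenarios$baseline, file.path(dir, "baseline.asc"))
  futures_cfg <- purrr::imap(scenarios$futures, function(f, i) {
    p <- file.path(dir, sprintf("future_%02d.asc", i))
    write_climate_grid(f, p)
    list(path = p, gcm = scenarios$labels$gcm[i], ssp = scenarios$labels$ssp[i])
  })

  derive_seed <- function(salt)
    as.integer((as.numeric(seed) * 1009 + salt) %% 2147483647)
  tiers <- rep(c("low", "moderate", "high"), each = n_per_tier)
  specs <- purrr::imap(tiers, function(tier, i)
    make_species(scenarios, target_tier = tier,
                 species_id = sprintf("%s_%02d", tier, i),
                 seed = derive_seed(i)))
  write_ranges(purrr::map(specs, "range"), file.path(dir, "ranges.geojson"))

  set.seed(seed)
  orders <- c("Chiroptera", "Dasyuromorphia", "Diprotodontia",
              "Peramelemorphia", "Rodentia")
  iucns <- c("LC", "NT", "VUL", "END", "CE")
  truth <- purrr::map(specs, function(s) as_tibble(
    s$truth[c("species_id", "tier", "target_tier", "mean_current",
              "se_current", "mean_historical", "se_historical",
              "tm_historical", "tm_current", "delta_tm", "area_fraction")])) |>
    purrr::list_rbind()
  traits <- tibble(
    species_id = truth$species_id,
    order = sample(orders, nrow(truth), replace = TRUE),
    iucn = sample(iucns, nrow(truth), replace = TRUE),
    log_body_mass = round(runif(nrow(truth), 1, 4.5), 3),
    pct_arid = round(runif(nrow(truth), 20, 100), 1),
    pct_remnant = round(runif(nrow(truth), 1, 60), 1)
  )
  readr::write_csv(traits, file.path(dir, "traits.csv"))
  # study effort mirroring the research-bias structure: high-risk species
  # least studied on average
  lambda <- c(low = 6.3, moderate = 4.7, high = 1.4)
  studies <- tibble(species_id = truth$species_id,
                    n_studies = stats::rpois(nrow(truth),
                                             lambda[as.character(truth$tier)]))
  readr::write_csv(studies, file.path(dir, "studies.csv"))

  site_pieces <- purrr::imap(specs, function(s, i)
    make_sites(scenarios, s, n = n_sites_per_species,
               seed = derive_seed(5000L + i)))
  sites <- purrr::map(site_pieces, "sites") |> purrr::list_rbind()
  readr::write_csv(sites, file.path(dir, "sites.csv"))
  site_truth <- purrr::map2(site_pieces, purrr::map_chr(specs, ~ .x$truth$species_id),
                            function(sp, id) dplyr::mutate(sp$truth,
                                                           species_id = id,
                                                           .before = 1)) |>
    purrr::list_rbind()
  readr::write_csv(truth, file.path(dir, "truth_species.csv"))

  cfg <- list(baseline = file.path(dir, "baseline.asc"),
              futures = futures_cfg,
              ranges = file.path(dir, "ranges.geojson"),
              sites = file.path(dir, "sites.csv"),
              traits = file.path(dir, "traits.csv"),
              studies = file.path(dir, "studies.csv"),
              out_dir = file.path(dir, "out"),
              seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(config = cfg_path, truth = truth, site_truth = site_truth))
}
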