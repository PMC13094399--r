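#' Species range pair (historical + current polygons)
#'
#' @param species_id Species identifier.
#' @param historical,current [heat_poly] polygons for the two epochs. Both
#'   must have positive area under the even-odd rule.
#' @return An object of class `species_range`.
#' @export
species_range <- function(species_id, historical, current) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            inherits(historical, "heat_poly"), inherits(current, "heat_poly"))
  if (poly_area(historical) <= 0 || poly_area(current) <= 0)
    stop("range polygons for ", species_id, " must have positive area",
         call. = FALSE)
  structure(list(species_id = species_id, historical = historical,
                 current = current),
            class = "species_range")
}

#' @export
print.species_range <- function(x, ...) {
  cat(sprintf("<species_range> %s\n  historical area %.6g | current area %.6g\n",
              x$species_id, poly_area(x$historical), poly_area(x$current)))
  invisible(x)
}

geojson_geom_to_poly <- function(geom) {
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    m
  }
  rings <- switch(
    geom$type,
    Polygon = lapply(geom$coordinates, ring_mat),
    MultiPolygon = unlist(lapply(geom$coordinates,
                                 function(p) lapply(p, ring_mat)),
                          recursive = FALSE),
    stop("unsupported geometry type: ", geom$type, call. = FALSE)
  )
  heat_poly(rings)
}

poly_to_geojson_geom <- function(poly) {
  list(type = "MultiPolygon",
       coordinates = lapply(poly$rings, function(r) {
         r <- rbind(r, r[1L, ])
         list(lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ])))
       }))
}

#' Read species ranges from GeoJSON
#'
#' Expects a FeatureCollection whose features carry `species_id` and
#' `epoch` (`"historical"` or `"current"`) properties with Polygon or
#' MultiPolygon geometry. Features of one species/epoch are combined;
#' species missing either epoch are reported with a warning and dropped.
#' Self-intersecting rings are accepted and interpreted under the even-odd
#' fill rule (see [heat_poly]).
#'
#' @param path Path to a GeoJSON file.
#' @return A list of [species_range] objects (possibly empty), named by
#'   species id.
#' @export
read_ranges <- function(path) {
  if (!file.exists(path)) stop("cannot read ranges: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("schema error: expected a GeoJSON FeatureCollection", call. = FALSE)
  feats <- gj$features
  recs <- lapply(feats, function(f) {
    pr <- f$properties
    if (is.null(pr$species_id) || is.null(pr$epoch))
      stop("schema error: features must carry `species_id` and `epoch` properties",
           call. = FALSE)
    if (!pr$epoch %in% c("historical", "current"))
      stop("schema error: epoch must be 'historical' or 'current', got ",
           pr$epoch, call. = FALSE)
    list(species_id = pr$species_id, epoch = pr$epoch,
         poly = geojson_geom_to_poly(f$geometry))
  })
  ids <- vapply(recs, `[[`, character(1), "species_id")
  out <- list()
  for (id in unique(ids)) {
    sub <- recs[ids == id]
    epochs <- vapply(sub, `[[`, character(1), "epoch")
    if (!all(c("historical", "current") %in% epochs)) {
      warning("species ", id, " lacks epoch(s): ",
              paste(setdiff(c("historical", "current"), epochs), collapse = ", "),
              " - excluded", call. = FALSE)
      next
    }
    combine <- function(ep) {
      polys <- lapply(sub[epochs == ep], `[[`, "poly")
      Reduce(poly_union, polys)
    }
    out[[id]] <- species_range(id, combine("historical"), combine("current"))
  }
  out
}

#' Write species ranges to GeoJSON
#'
#' @param ranges A list of [species_range] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranges <- function(ranges, path) {
  feats <- list()
  for (rg in ranges) {
    for (ep in c("historical", "current")) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(species_id = rg$species_id, epoch = ep),
        geometry = poly_to_geojson_geom(rg[[ep]])
      )
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read translocation sites from CSV
#'
#' Expects columns `species_id`, `site_name`, `lon`, `lat`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of site records.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("cannot read sites: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species_id", "site_name", "lon", "lat")
  if (!all(need %in% names(x)))
    stop("schema error: site CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  as_tibble(x[, need])
}
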