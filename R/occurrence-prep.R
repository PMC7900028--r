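#' Clean and temporally filter occurrence records
#'
#' Applies the standard coordinate-cleaning battery and a publication-year
#' window. Records failing any enabled test are dropped; exact duplicate
#' rows collapse to one. Records with missing year are dropped by default
#' (a year filter cannot vouch for them), controllable via
#' `drop_missing_year`.
#'
#' @param occ Occurrence tibble with columns `species`, `lon`, `lat` and
#'   optionally `year`, `source`.
#' @param year_min,year_max Inclusive year window (default 1970-2020).
#' @param tests Cleaning tests to enable, any of `"zero_coords"` (both
#'   coordinates 0), `"equal_latlon"` (`|lat| == |lon|` within 1e-6, a
#'   classic transposition artifact), `"duplicates"` (exact duplicate rows).
#' @param drop_missing_year Drop records with `NA` year?
#' @return Filtered tibble (possibly empty, with a warning).
#' @export
filter_records <- function(occ, year_min = 1970, year_max = 2020,
                           tests = c("zero_coords", "equal_latlon",
                                     "duplicates"),
                           drop_missing_year = TRUE) {
  if (year_min > year_max) stop_invalid("`year_min` must be <= `year_max`")
  tests <- match.arg(tests, several.ok = TRUE)
  out <- tibble::as_tibble(occ)
  if (any(abs(out$lon) > 180 | abs(out$lat) > 90, na.rm = TRUE)) {
    stop_invalid("coordinates out of WGS84 bounds")
  }
  if (!"year" %in% names(out)) out$year <- NA_integer_
  keep_year <- !is.na(out$year) & out$year >= year_min & out$year <= year_max
  if (!drop_missing_year) keep_year <- keep_year | is.na(out$year)
  out <- out[keep_year, ]
  if ("zero_coords" %in% tests) {
    out <- dplyr::filter(out, !(.data$lon == 0 & .data$lat == 0))
  }
  if ("equal_latlon" %in% tests) {
    out <- dplyr::filter(out, abs(abs(.data$lat) - abs(.data$lon)) > 1e-6)
  }
  if ("duplicates" %in% tests) out <- dplyr::distinct(out)
  if (nrow(out) == 0L) warn("all records removed by filtering")
  out
}

#' Spatially disaggregate records to one per graticule cell
#'
#' Keeps at most one record per `cell_size` x `cell_size` graticule cell
#' (half-open cells anchored at lon -180, lat -90). The first record of each
#' cell in input order is kept, which makes the operation idempotent.
#'
#' @param occ Occurrence tibble (`lon`, `lat`, ...).
#' @param cell_size Cell size in arc-minutes (default 2.5').
#' @return Subset tibble with at most one record per cell.
#' @export
disaggregate <- function(occ, cell_size = 2.5) {
  if (cell_size <= 0) stop_invalid("`cell_size` must be > 0")
  cs <- cell_size / 60
  occ <- tibble::as_tibble(occ)
  ci <- floor((occ$lon + 180) / cs)
  cj <- floor((occ$lat + 90) / cs)
  occ[!duplicated(paste(ci, cj)), ]
}

haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Distance rarefaction (spatial thinning)
#'
#' Greedy thinning: records are put in a canonical order, shuffled with the
#' seed, then accepted one by one if their great-circle distance (haversine,
#' Earth radius 6371 km) to every already-accepted record is at least
#' `min_dist_km`. The output is a subset of the input with all pairwise
#' distances >= the threshold; given the seed it is invariant to input row
#' order. Greedy thinning does not maximize the retained count (that
#' problem is NP-hard) but matches common practice.
#'
#' @param occ Occurrence tibble (`lon`, `lat`, ...).
#' @param min_dist_km Minimum pairwise distance in km (default 10).
#' @param seed Integer seed for the shuffle.
#' @return Thinned tibble.
#' @export
rarefy <- function(occ, min_dist_km = 10, seed = 1) {
  if (min_dist_km <= 0) stop_invalid("`min_dist_km` must be > 0")
  occ <- tibble::as_tibble(occ)
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  canon <- order(occ$lon, occ$lat)
  ord <- with_seed(seed, canon[sample.int(n)])
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0L ||
        all(haversine_km(occ$lon[i], occ$lat[i],
                         occ$lon[accepted], occ$lat[accepted]) >= min_dist_km)) {
      accepted <- c(accepted, i)
    }
  }
  occ[sort(accepted), ]
}

#' Background region polygons
#'
#' A multipolygon in WGS84 used to delimit the calibration background (the
#' species' original biome in the source analysis).
#'
#' @param rings List of two-column matrices (lon, lat), one per ring;
#'   rings need not be closed.
#' @param name Region label.
#' @return A `background_region` object.
#' @export
background_region <- function(rings, name = "background") {
  if (is.matrix(rings)) rings <- list(rings)
  if (length(rings) == 0L) stop_invalid("region must have at least one ring")
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 3L) {
      stop_invalid("each ring needs >= 3 (lon, lat) vertices")
    }
    unname(r)
  })
  structure(list(rings = rings, name = name), class = "background_region")
}

#' @export
print.background_region <- function(x, ...) {
  cat(sprintf("<background_region> '%s': %d ring(s)\n", x$name,
              length(x$rings)))
  invisible(x)
}

#' Read a (Multi)Polygon from GeoJSON
#'
#' Supports Feature/FeatureCollection/Polygon/MultiPolygon geometries;
#' only the outer structure is interpreted (all rings participate in the
#' even-odd point-in-polygon rule, so holes are honored).
#'
#' @param path GeoJSON file path.
#' @return A [background_region()].
#' @export
read_geojson_region <- function(path) {
  g <- jsonlite::read_json(path)
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
  name <- "background"
  if (identical(g$type, "Feature")) {
    if (!is.null(g$properties$name)) name <- g$properties$name
    g <- g$geometry
  }
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  }
  rings <- switch(g$type,
    Polygon = lapply(g$coordinates, ring_mat),
    MultiPolygon = unlist(lapply(g$coordinates,
                                 function(poly) lapply(poly, ring_mat)),
                          recursive = FALSE),
    stop_invalid(paste("unsupported GeoJSON geometry:", g$type))
  )
  background_region(rings, name = name)
}

# Even-odd point-in-polygon over all rings (NA-separated boundary for
# mgcv::in.out).
points_in_region <- function(region, lon, lat) {
  bnd <- do.call(rbind, lapply(region$rings, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(lon, lat))
}

#' Sample background points within a region
#'
#' Samples cells of the stack whose centers fall inside the region polygons
#' and are not nodata, uniformly with replacement, and returns the cell
#' centers as pseudo-occurrence records. With enough points the per-cell
#' counts are multinomial-uniform over the valid cells.
#'
#' @param region A [background_region()].
#' @param stack An [env_stack()].
#' @param n_points Number of points (default 10000).
#' @param seed Integer seed.
#' @return Occurrence tibble (`species = "background"`).
#' @export
sample_background <- function(region, stack, n_points = 10000, seed = 1) {
  cc <- cell_centers(stack)
  ok <- points_in_region(region, cc$lon, cc$lat) & as.vector(stack$mask)
  if (!any(ok)) stop_degenerate("region contains no valid cells")
  idx <- which(ok)
  with_seed(seed, {
    pick <- idx[sample.int(length(idx), n_points, replace = TRUE)]
    tibble::tibble(
      species = "background",
      lon = cc$lon[pick], lat = cc$lat[pick],
      year = NA_integer_, source = "background"
    )
  })
}

#' Read / write occurrence CSV
#'
#' The exchange schema is `species, lon, lat, year, source`.
#'
#' @param path CSV path.
#' @return `read_occurrences()` returns a tibble.
#' @export
read_occurrences <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df))) {
    stop_invalid("occurrence CSV needs columns species, lon, lat")
  }
  df
}

#' @rdname read_occurrences
#' @param occ Occurrence tibble.
#' @export
write_occurrences <- function(occ, path) {
  write.csv(occ, path, row.names = FALSE)
  invisible(path)
}
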