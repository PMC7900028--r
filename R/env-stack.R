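#' Co-registered environmental raster stack
#'
#' An `env_stack` bundles named environmental layers that share one grid:
#' equal dimensions, one geographic extent (WGS84 decimal degrees, north-up)
#' and one nodata mask. It is the in-memory analogue of a multi-layer
#' bioclimatic raster (bio1...bio19) and the common currency of the whole
#' pipeline: virtual species are defined on it, occurrences are extracted
#' from it, and suitability maps are predicted over it.
#'
#' Layers are numeric matrices with row 1 the northernmost row. Cell
#' membership is half-open, `[edge, edge + size)`, anchored at the west/south
#' extent edges.
#'
#' @param layers Named list of numeric matrices, all with identical
#'   dimensions. `NA` cells are treated as nodata in every layer.
#' @param extent Numeric vector `c(xmin, xmax, ymin, ymax)` in decimal
#'   degrees.
#' @return An object of class `env_stack`.
#' @examples
#' st <- env_stack(list(bio1 = matrix(1:12, 3), bio12 = matrix(12:1, 3)),
#'                 extent = c(-50, -46, -25, -22))
#' dim(st)
#' head(as_tibble(st))
#' @export
env_stack <- function(layers, extent = c(-50, -40, -25, -15)) {
  if (!is.list(layers) || length(layers) == 0L || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    stop_invalid("`layers` must be a non-empty named list of matrices")
  }
  dims <- lapply(layers, dim)
  if (any(!vapply(layers, is.matrix, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_invalid("all layers must be matrices with identical dimensions")
  }
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop_invalid("`extent` must be c(xmin, xmax, ymin, ymax) with positive spans")
  }
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  structure(
    list(layers = layers, extent = extent, mask = mask),
    class = "env_stack"
  )
}

#' @export
dim.env_stack <- function(x) dim(x$layers[[1]])

n_layers <- function(stack) length(stack$layers)

#' Layer names of a stack
#' @param stack An [env_stack()].
#' @return Character vector of layer names.
#' @export
layer_names <- function(stack) names(stack$layers)

res_xy <- function(stack) {
  d <- dim(stack)
  c((stack$extent[2] - stack$extent[1]) / d[2],
    (stack$extent[4] - stack$extent[3]) / d[1])
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<env_stack> %d layers, %d x %d cells\n", n_layers(x), d[1], d[2]))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  cat("  layers:", paste(layer_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Cell-center coordinates of a stack
#'
#' @param stack An [env_stack()].
#' @return Tibble with `row`, `col`, `lon`, `lat`, one row per cell in
#'   column-major order (the cell order used by [env_values()]).
#' @export
cell_centers <- function(stack) {
  d <- dim(stack)
  rs <- res_xy(stack)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  tibble::tibble(
    row = grid$row,
    col = grid$col,
    lon = stack$extent[1] + (grid$col - 0.5) * rs[1],
    lat = stack$extent[4] - (grid$row - 0.5) * rs[2]
  )
}

#' Environmental values as a cells-by-layers matrix
#'
#' @param stack An [env_stack()].
#' @param valid_only Drop nodata cells?
#' @return Numeric matrix, one column per layer; rows in column-major cell
#'   order (matching [cell_centers()]).
#' @export
env_values <- function(stack, valid_only = FALSE) {
  m <- vapply(stack$layers, as.vector, numeric(prod(dim(stack))))
  if (valid_only) m <- m[as.vector(stack$mask), , drop = FALSE]
  m
}

#' @rdname env_stack
#' @param x An `env_stack`.
#' @param ... Unused.
#' @export
as_tibble.env_stack <- function(x, ...) {
  out <- cell_centers(x)
  vals <- tibble::as_tibble(as.data.frame(env_values(x)))
  dplyr::bind_cols(out, vals, tibble::tibble(valid = as.vector(x$mask)))
}

# Half-open cell lookup; points outside the extent map to NA.
cell_row_col <- function(stack, lon, lat) {
  d <- dim(stack)
  rs <- res_xy(stack)
  col <- floor((lon - stack$extent[1]) / rs[1]) + 1L
  row_from_s <- floor((lat - stack$extent[3]) / rs[2])
  row <- d[1] - row_from_s
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract environmental values at point locations
#'
#' @param stack An [env_stack()].
#' @param lon,lat Coordinate vectors (decimal degrees, WGS84).
#' @param layers Layer names to extract (default all).
#' @return Matrix of values, one row per point; `NA` rows for points outside
#'   the extent or on nodata cells.
#' @export
extract_env <- function(stack, lon, lat, layers = layer_names(stack)) {
  rc <- cell_row_col(stack, lon, lat)
  out <- vapply(layers, function(nm) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(rc$row)
    v[ok] <- stack$layers[[nm]][cbind(rc$row[ok], rc$col[ok])]
    v
  }, numeric(length(lon)))
  if (length(lon) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, layers))
  out
}

#' Per-cell areas in square kilometres
#'
#' Uses the small-cell spherical approximation
#' `(111.320 * dlon * cos(lat)) * (110.574 * dlat)` at the cell-center
#' latitude, adequate for the desk-scale grids this package targets.
#'
#' @param stack An [env_stack()] (or any object carrying `extent` and a
#'   matrix payload of the same shape).
#' @param dims Optional `c(nrow, ncol)` when `stack` is a bare extent.
#' @return Matrix of cell areas (km^2) matching the grid shape.
#' @export
cell_areas_km2 <- function(stack, dims = NULL) {
  extent <- stack$extent
  d <- if (is.null(dims)) dim(stack$layers[[1]]) else dims
  dlon <- (extent[2] - extent[1]) / d[2]
  dlat <- (extent[4] - extent[3]) / d[1]
  lat <- extent[4] - (seq_len(d[1]) - 0.5) * dlat
  w <- 111.320 * dlon * cos(lat * pi / 180)
  h <- 110.574 * dlat
  matrix(rep(w * h, d[2]), nrow = d[1])
}

#' Write / read a stack as ESRI ASCII grids
#'
#' One plain-text `.asc` file per layer plus a JSON sidecar recording layer
#' names and, when supplied, the generating seed. The ASCII grid is the
#' text-based exchange format used here in place of GeoTIFF.
#'
#' @param stack An [env_stack()].
#' @param dir Output directory (created if needed).
#' @param seed Optional integer recorded in the sidecar.
#' @return `write_env_stack()` returns the sidecar path invisibly;
#'   `read_env_stack()` returns an [env_stack()].
#' @export
write_env_stack <- function(stack, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rs <- res_xy(stack)
  if (abs(rs[1] - rs[2]) > 1e-9) {
    warn("ASCII grid assumes square cells; writing with cellsize = x resolution")
  }
  d <- dim(stack)
  for (nm in layer_names(stack)) {
    path <- file.path(dir, paste0(nm, ".asc"))
    con <- file(path, "w")
    writeLines(c(
      sprintf("ncols %d", d[2]),
      sprintf("nrows %d", d[1]),
      sprintf("xllcorner %.10g", stack$extent[1]),
      sprintf("yllcorner %.10g", stack$extent[3]),
      sprintf("cellsize %.10g", rs[1]),
      "NODATA_value -9999"
    ), con)
    m <- stack$layers[[nm]]
    m[is.na(m)] <- -9999
    write.table(m, con, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  sidecar <- file.path(dir, "stack.json")
  jsonlite::write_json(
    list(layers = layer_names(stack), extent = stack$extent, seed = seed),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

#' @rdname write_env_stack
#' @param paths Character vector of `.asc` files; layer names are taken from
#'   file names.
#' @export
read_env_stack <- function(paths) {
  layers <- lapply(paths, function(p) {
    hdr <- readLines(p, n = 6L)
    kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
    h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
    vals <- scan(p, skip = 6L, quiet = TRUE)
    m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
    m[m == h[["nodata_value"]]] <- NA
    attr(m, "hdr") <- h
    m
  })
  h <- attr(layers[[1]], "hdr")
  ext <- c(h[["xllcorner"]], h[["xllcorner"]] + h[["ncols"]] * h[["cellsize"]],
           h[["yllcorner"]], h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]])
  layers <- lapply(layers, function(m) { attr(m, "hdr") <- NULL; m })
  names(layers) <- sub("\\.asc$", "", basename(paths))
  env_stack(layers, extent = ext)
}

#' Plot one layer of a stack
#'
#' @param object An [env_stack()].
#' @param layer Layer name (default the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.env_stack <- function(object, layer = layer_names(object)[1], ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = layer, x = "Longitude", y = "Latitude")
}

#' Moran's I spatial autocorrelation of a grid layer
#'
#' Rook-neighbour Moran's I, used to verify that generated climate fields
#' carry the requested spatial autocorrelation.
#'
#' @param m Numeric matrix.
#' @return Moran's I (scalar).
#' @export
moran_i <- function(m) {
  z <- m - mean(m)
  num <- 0
  w <- 0
  nr <- nrow(z); nc <- ncol(z)
  num <- num + 2 * sum(z[-nr, ] * z[-1, ]); w <- w + 2 * (nr - 1) * nc
  num <- num + 2 * sum(z[, -nc] * z[, -1]); w <- w + 2 * nr * (nc - 1)
  (length(z) / w) * num / sum(z^2)
}
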