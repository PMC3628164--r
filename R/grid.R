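#' Regular latitude-longitude grid specification
#'
#' Defines the prediction raster: a north-up regular grid in geographic
#' (WGS84) coordinates with pixel-centre registration.  Row 1 is the
#' southernmost row; values on a grid are stored as an `n_rows x n_cols`
#' matrix, vectorised column-major (R's native order).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param origin_lat,origin_lon Latitude/longitude of the south-west corner
#'   of the grid (degrees, WGS84).
#' @param cell_size Pixel edge in decimal degrees (> 0).
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(10, 12, origin_lat = 8, origin_lon = -6, cell_size = 0.5)
#' head(pixel_centers(g))
#' @export
grid_spec <- function(n_rows, n_cols, origin_lat = 4, origin_lon = -14,
                      cell_size = 0.5) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  assert_scalar_num(origin_lat, "origin_lat", -90, 90)
  assert_scalar_num(origin_lon, "origin_lon", -180, 180)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_lat = origin_lat, origin_lon = origin_lon,
         cell_size = cell_size,
         n_pixels = as.integer(n_rows) * as.integer(n_cols)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %.4g deg cells, SW corner (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lat, x$origin_lon))
  invisible(x)
}

#' Pixel-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `row`, `col`, `lat`, `lon`, one row per
#'   pixel in column-major (vectorisation) order.
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  tibble::tibble(
    row = row, col = col,
    lat = grid$origin_lat + (row - 0.5) * grid$cell_size,
    lon = grid$origin_lon + (col - 0.5) * grid$cell_size)
}

#' Pixel areas in km^2
#'
#' Spherical-cap approximation on a sphere of radius 6371.0088 km; area
#' varies by row through the cosine of the centre latitude.
#'
#' @param grid A [grid_spec()].
#' @return An `n_rows x n_cols` matrix of areas (km^2).
#' @export
pixel_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  km_per_deg <- pi * earth_radius_km() / 180
  lat <- grid$origin_lat + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  a <- (grid$cell_size * km_per_deg)^2 * cos(lat * pi / 180)
  matrix(rep(a, grid$n_cols), nrow = grid$n_rows)
}

grid_matrix <- function(values, grid) {
  stopifnot(length(values) == grid$n_pixels)
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Write a grid-shaped matrix as an ESRI ASCII raster
#'
#' Plain-text raster interchange (`.asc`): north-up, WGS84 geographic
#' coordinates, pixel-centre registration documented via the lower-left
#' corner header.  Row 1 of the matrix (southernmost) is written last, as
#' the format requires.
#'
#' @param values `n_rows x n_cols` numeric matrix (row 1 = south).
#' @param grid The [grid_spec()] the matrix lives on.
#' @param path Output file path.
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, digits = 10) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10f", grid$origin_lon),
    sprintf("yllcorner %.10f", grid$origin_lat),
    sprintf("cellsize %.10f", grid$cell_size),
    "NODATA_value -9999")
  v <- values
  v[!is.finite(v)] <- -9999
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster written by [write_ascii_grid()]
#'
#' @param path File path.
#' @return A list with `grid` (a [grid_spec()]) and `values` (matrix,
#'   row 1 = south; NODATA as `NA`).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1L)
  val <- vapply(hdr, `[`, "", 2L)
  h <- stats::setNames(as.numeric(val), tolower(key))
  grid <- grid_spec(h[["nrows"]], h[["ncols"]],
                    origin_lat = h[["yllcorner"]], origin_lon = h[["xllcorner"]],
                    cell_size = h[["cellsize"]])
  rows <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == h[["nodata_value"]]] <- NA_real_
  dimnames(m) <- NULL
  list(grid = grid, values = m)
}

#' Sum-aggregate a fine raster to a coarser grid
#'
#' Conservative pixel-sum aggregation of a population raster whose
#' resolution is an integer multiple finer than the target grid (e.g. 1 km
#' counts onto a 5 km prediction grid).  Fine pixels are assigned to the
#' coarse pixel containing their centre.
#'
#' @param values Fine-resolution matrix (row 1 = south).
#' @param factor Integer aggregation factor (fine pixels per coarse pixel
#'   edge).
#' @return A matrix with dimensions `dim(values) / factor`.
#' @examples
#' aggregate_sum(matrix(1:4, 2, 2), 2)  # one coarse pixel holding 10
#' @export
aggregate_sum <- function(values, factor) {
  stopifnot(is.matrix(values), factor >= 1, factor == as.integer(factor))
  factor <- as.integer(factor)
  if (nrow(values) %% factor != 0 || ncol(values) %% factor != 0)
    stop("matrix dimensions must be multiples of `factor`", call. = FALSE)
  nr <- nrow(values) %/% factor
  nc <- ncol(values) %/% factor
  ri <- (seq_len(nrow(values)) - 1L) %/% factor + 1L
  ci <- (seq_len(ncol(values)) - 1L) %/% factor + 1L
  out <- matrix(0, nr, nc)
  for (j in seq_len(ncol(values))) {
    out[, ci[j]] <- out[, ci[j]] + rowsum(values[, j], ri)[, 1L]
  }
  out
}
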