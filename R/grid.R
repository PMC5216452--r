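#' Grid conventions and geodesic utilities
#'
#' The whole pipeline works on one geographic (lon/lat) analysis grid at a
#' fixed resolution, by default 10 arcminutes. Cells are registered by their
#' lower-left corner and have half-open footprints
#' `[lon0, lon0 + res) x [lat0, lat0 + res)`, so a point on a shared edge
#' belongs to exactly one cell and deduplication at cell boundaries is
#' deterministic. Cells are addressed by a single integer index in
#' column-major order (row 1 = southernmost row).
#'
#' @name grid-conventions
NULL

EARTH_RADIUS_KM <- 6371

#' Define the analysis grid
#'
#' @param min_lon,min_lat Lower-left corner of the grid, decimal degrees.
#' @param n_rows,n_cols Grid dimensions (rows run south to north).
#' @param cell_size Cell edge in arcminutes (default 10).
#' @param land_mask Logical matrix (`n_rows` x `n_cols`) or vector of length
#'   `n_rows * n_cols`; `TRUE` marks land (analysis) cells. Default: all land.
#'   The study-area mask is an input, never computed.
#' @return A `grid_definition` object.
#' @export
grid_definition <- function(min_lon, min_lat, n_rows, n_cols,
                            cell_size = 10, land_mask = NULL) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  res <- cell_size / 60
  if (min_lat + n_rows * res > 90 || min_lat < -90)
    stop("grid extends beyond +/-90 degrees latitude")
  if (is.null(land_mask)) land_mask <- rep(TRUE, n_rows * n_cols)
  land_mask <- as.logical(land_mask)
  if (length(land_mask) != n_rows * n_cols)
    stop("land_mask must have n_rows * n_cols entries")
  structure(list(min_lon = min_lon, min_lat = min_lat,
                 n_rows = n_rows, n_cols = n_cols,
                 cell_size = cell_size, res_deg = res,
                 land_mask = land_mask),
            class = "grid_definition")
}

#' @export
print.grid_definition <- function(x, ...) {
  cat(sprintf("<grid_definition> %d x %d cells at %g', origin (%g, %g), %d land cells\n",
              x$n_rows, x$n_cols, x$cell_size, x$min_lon, x$min_lat,
              sum(x$land_mask)))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Land-cell indices of a grid
#' @param grid A `grid_definition`.
#' @return Integer vector of cell indices where the mask is `TRUE`.
#' @export
land_cells <- function(grid) which(grid$land_mask)

#' Locate the grid cell containing a point
#'
#' Half-open convention: a point exactly on a cell's lower or left edge
#' belongs to that cell; a point on the grid's maximum-lon/lat boundary is
#' out of extent.
#'
#' @param lon,lat Coordinates in decimal degrees (vectorized).
#' @param grid A `grid_definition`.
#' @return Integer cell indices (column-major, row 1 southernmost).
#' @export
cell_of <- function(lon, lat, grid) {
  col <- floor((lon - grid$min_lon) / grid$res_deg) + 1
  row <- floor((lat - grid$min_lat) / grid$res_deg) + 1
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%g, %g) is outside the grid extent", lon[i], lat[i]))
  }
  as.integer((col - 1) * grid$n_rows + row)
}

#' Row/column and centre coordinates of cells
#' @param cell Integer cell indices.
#' @param grid A `grid_definition`.
#' @return `cell_rowcol`: two-column integer matrix (row, col).
#'   `cell_center`: data.frame with `lon`, `lat` of cell centres.
#' @export
cell_rowcol <- function(cell, grid) {
  cell <- as.integer(cell)
  row <- (cell - 1L) %% grid$n_rows + 1L
  col <- (cell - 1L) %/% grid$n_rows + 1L
  cbind(row = row, col = col)
}

#' @rdname cell_rowcol
#' @export
cell_center <- function(cell, grid) {
  rc <- cell_rowcol(cell, grid)
  data.frame(lon = grid$min_lon + (rc[, "col"] - 0.5) * grid$res_deg,
             lat = grid$min_lat + (rc[, "row"] - 0.5) * grid$res_deg)
}

#' Spherical area of a grid cell
#'
#' Spherical-Earth approximation `(delta * R)^2 * cos(lat)` with
#' `R = 6371` km; at 50 N a 10' cell is about 220 km^2.
#'
#' @param lat_centre Cell-centre latitude, degrees; must satisfy `|lat| < 90`.
#' @param cell_size Cell edge in arcminutes.
#' @return Area in km^2 (vectorized over `lat_centre`).
#' @export
cell_area_km2 <- function(lat_centre, cell_size = 10) {
  if (any(abs(lat_centre) >= 90)) stop("polar cell: |lat_centre| must be < 90")
  d <- cell_size / 60 * pi / 180
  (d * EARTH_RADIUS_KM)^2 * cos(lat_centre * pi / 180)
}

#' Great-circle distance
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorized with the
#' usual recycling.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Single-layer raster on the analysis grid
#'
#' Values are stored as one numeric per cell (column-major). Values must be
#' finite on land; off-mask cells may be `NA`.
#'
#' @param grid A `grid_definition`.
#' @param values Numeric vector of length `n_rows * n_cols`.
#' @param name Layer label.
#' @return A `raster_layer` object.
#' @export
raster_layer <- function(grid, values, name = "layer") {
  stopifnot(inherits(grid, "grid_definition"))
  values <- as.numeric(values)
  if (length(values) != n_cells(grid))
    stop("values must have one entry per grid cell")
  if (any(!is.finite(values[grid$land_mask])))
    stop(sprintf("layer '%s' has non-finite values on land cells", name))
  structure(list(grid = grid, name = name, values = values),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[x$grid$land_mask]
  cat(sprintf("<raster_layer '%s'> %d x %d, land range [%.4g, %.4g]\n",
              x$name, x$grid$n_rows, x$grid$n_cols, min(v), max(v)))
  invisible(x)
}

#' Raster and occurrence CSV exchange
#'
#' Plain-text exchange formats so no geospatial stack is required: rasters
#' travel as `row,col,value` CSV (land cells only; grid geometry in `#`
#' header comments), occurrences as `species,lon,lat` CSV.
#'
#' @param layer A `raster_layer`.
#' @param path File path.
#' @return `read_raster_csv` returns a `raster_layer`; writers return the
#'   path invisibly.
#' @export
write_raster_csv <- function(layer, path) {
  g <- layer$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid min_lon=%.10g min_lat=%.10g n_rows=%d n_cols=%d cell_size=%.10g",
                     g$min_lon, g$min_lat, g$n_rows, g$n_cols, g$cell_size), con)
  writeLines(sprintf("# name=%s", layer$name), con)
  keep <- which(g$land_mask & !is.na(layer$values))
  rc <- cell_rowcol(keep, g)
  df <- data.frame(row = rc[, "row"], col = rc[, "col"],
                   value = format(layer$values[keep], digits = 17))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param grid Grid to attach on read; if `NULL`, rebuilt from the header
#'   (mask = cells present in the file).
#' @export
read_raster_csv <- function(path, grid = NULL) {
  hdr <- readLines(path, n = 2)
  m <- regmatches(hdr[1], gregexpr("[a-z_]+=[-0-9.eE+]+", hdr[1]))[[1]]
  kv <- stats::setNames(as.numeric(sub(".*=", "", m)), sub("=.*", "", m))
  name <- sub("^# name=", "", hdr[2])
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(grid)) {
    grid <- grid_definition(kv[["min_lon"]], kv[["min_lat"]],
                            kv[["n_rows"]], kv[["n_cols"]], kv[["cell_size"]],
                            land_mask = rep(FALSE, kv[["n_rows"]] * kv[["n_cols"]]))
    idx <- (df$col - 1L) * grid$n_rows + df$row
    grid$land_mask[idx] <- TRUE
  } else {
    idx <- (df$col - 1L) * grid$n_rows + df$row
  }
  vals <- rep(NA_real_, n_cells(grid))
  vals[idx] <- df$value
  raster_layer(grid, vals, name = name)
}

#' @rdname write_raster_csv
#' @param records Data frame with columns `species`, `lon`, `lat`.
#' @export
write_occurrences_csv <- function(records, path) {
  utils::write.csv(records[, c("species", "lon", "lat")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species,lon,lat")
  df[, need]
}
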