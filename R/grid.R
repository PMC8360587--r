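# Equal-area analysis grid: definition, point indexing, and gridding of
# occurrence records. All layers (ranges, countries, occurrences) are indexed
# on the same grid so that indices computed from them are commensurable.

#' Define an equal-area analysis grid
#'
#' Builds the square-celled, equal-area grid on which all layers (species
#' ranges, country boundaries, occurrence records) are indexed. Cells are
#' square in projected coordinates (kilometres) under a cylindrical
#' equal-area projection; cell identifiers are row-major integers starting at
#' 0 in the lower-left corner.
#'
#' @param cell_size_km Edge length of a grid cell in kilometres (e.g. 110,
#'   55, 27.5). Must be positive.
#' @param extent Projected bounding box `c(xmin, ymin, xmax, ymax)` in
#'   kilometres. Defaults to the full extent of the projection (whole globe).
#' @param projection Named equal-area projection. Currently `"behrmann"`
#'   (cylindrical equal-area, standard parallel 30 degrees) and `"cea"`
#'   (standard parallel 0, i.e. Lambert cylindrical) are supported.
#' @return An object of class `grid_spec`: a list with fields `projection`,
#'   `cell_size_km`, `x0`, `y0`, `n_cols`, `n_rows`. Partial edge cells are
#'   included (column/row counts are rounded up).
#' @examples
#' g <- build_grid(110, extent = c(0, 0, 660, 330))
#' n_cells(g)  # 18
#' @export
build_grid <- function(cell_size_km, extent = NULL, projection = "behrmann") {
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      !is.finite(cell_size_km) || cell_size_km <= 0) {
    stop("`cell_size_km` must be a single positive number", call. = FALSE)
  }
  proj <- match.arg(projection, c("behrmann", "cea"))
  if (is.null(extent)) extent <- projection_extent(proj)
  if (length(extent) != 4 || !all(is.finite(extent))) {
    stop("`extent` must be c(xmin, ymin, xmax, ymax) with finite values",
         call. = FALSE)
  }
  if (extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("`extent` is empty: xmax/ymax must exceed xmin/ymin", call. = FALSE)
  }
  n_cols <- as.integer(ceiling((extent[3] - extent[1]) / cell_size_km - 1e-9))
  n_rows <- as.integer(ceiling((extent[4] - extent[2]) / cell_size_km - 1e-9))
  structure(
    list(projection = proj, cell_size_km = cell_size_km,
         x0 = extent[1], y0 = extent[2],
         n_cols = n_cols, n_rows = n_rows),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Equal-area grid (%s): %d x %d cells of %g km (%d cells)\n",
              x$projection, x$n_cols, x$n_rows, x$cell_size_km, n_cells(x)))
  cat(sprintf("  origin (%.1f, %.1f) km\n", x$x0, x$y0))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A `grid_spec`.
#' @return Integer cell count (`n_cols * n_rows`).
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$n_cols * grid$n_rows
}

# Authalic earth radius in km; with the standard parallel it fixes the
# cylindrical equal-area forward/inverse maps.
.earth_radius_km <- 6371.007

.std_parallel <- function(projection) {
  switch(projection, behrmann = 30, cea = 0)
}

projection_extent <- function(projection) {
  k <- cos(.std_parallel(projection) * pi / 180)
  R <- .earth_radius_km
  c(-pi * R * k, -R / k, pi * R * k, R / k)
}

#' Project geographic coordinates to grid coordinates
#'
#' Forward cylindrical equal-area projection (km) used by the grid.
#'
#' @param lon,lat Numeric vectors of decimal degrees.
#' @param projection Projection name as in [build_grid()].
#' @return A two-column matrix of projected `x`, `y` in kilometres.
#' @export
project_lonlat <- function(lon, lat, projection = "behrmann") {
  proj <- match.arg(projection, c("behrmann", "cea"))
  k <- cos(.std_parallel(proj) * pi / 180)
  R <- .earth_radius_km
  cbind(x = R * (lon * pi / 180) * k, y = R * sin(lat * pi / 180) / k)
}

#' Inverse projection from grid coordinates to longitude/latitude
#' @param x,y Projected coordinates in kilometres.
#' @param projection Projection name as in [build_grid()].
#' @return A two-column matrix of `lon`, `lat` in decimal degrees.
#' @export
unproject_xy <- function(x, y, projection = "behrmann") {
  proj <- match.arg(projection, c("behrmann", "cea"))
  k <- cos(.std_parallel(proj) * pi / 180)
  R <- .earth_radius_km
  cbind(lon = (x / (R * k)) * 180 / pi,
        lat = asin(pmax(-1, pmin(1, y * k / R))) * 180 / pi)
}

#' Convert between cell identifiers and (row, col)
#'
#' Cell identifiers are row-major integers starting at 0: `cell = row *
#' n_cols + col`, with row 0 at the grid's lower edge.
#'
#' @param grid A `grid_spec`.
#' @param cell_id Integer vector of cell identifiers.
#' @return `cell_rowcol()`: a two-column matrix of 0-based `row`, `col`;
#'   `rowcol_cell()`: an integer vector of cell identifiers.
#' @export
cell_rowcol <- function(grid, cell_id) {
  stopifnot(inherits(grid, "grid_spec"))
  cell_id <- as.integer(cell_id)
  bad <- !is.na(cell_id) & (cell_id < 0 | cell_id >= n_cells(grid))
  if (any(bad)) {
    stop("cell identifiers outside grid extent: ",
         paste(utils::head(cell_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  cbind(row = cell_id %/% grid$n_cols, col = cell_id %% grid$n_cols)
}

#' @rdname cell_rowcol
#' @param row,col 0-based row and column indices.
#' @export
rowcol_cell <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  as.integer(row) * grid$n_cols + as.integer(col)
}

#' Projected bounding boxes of grid cells
#' @param grid A `grid_spec`.
#' @param cell_id Integer vector of cell identifiers.
#' @return A matrix with columns `xmin`, `ymin`, `xmax`, `ymax` (km).
#' @export
cell_bounds <- function(grid, cell_id) {
  rc <- cell_rowcol(grid, cell_id)
  cs <- grid$cell_size_km
  cbind(xmin = grid$x0 + rc[, "col"] * cs,
        ymin = grid$y0 + rc[, "row"] * cs,
        xmax = grid$x0 + (rc[, "col"] + 1) * cs,
        ymax = grid$y0 + (rc[, "row"] + 1) * cs)
}

#' Projected centres of grid cells
#' @inheritParams cell_bounds
#' @return A two-column matrix of cell-centre `x`, `y` (km).
#' @export
cell_centers <- function(grid, cell_id) {
  b <- cell_bounds(grid, cell_id)
  cbind(x = (b[, "xmin"] + b[, "xmax"]) / 2,
        y = (b[, "ymin"] + b[, "ymax"]) / 2)
}

#' Locate geographic points on the grid
#'
#' Assigns points to cells using half-open cell intervals
#' `[x_low, x_high) x [y_low, y_high)`, so a point on a shared edge belongs
#' to the cell on its lower-x (or lower-y) side and every point in the grid
#' extent belongs to exactly one cell.
#'
#' @param grid A `grid_spec`.
#' @param lon,lat Numeric vectors of decimal degrees (recycled to common
#'   length). Non-finite coordinates are an error; use [grid_occurrences()]
#'   to drop-and-count invalid records instead.
#' @return Integer vector of cell identifiers; `NA` for points outside the
#'   grid extent.
#' @export
locate_point <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  if (!all(is.finite(lon)) || !all(is.finite(lat))) {
    stop("non-finite coordinates in `lon`/`lat`", call. = FALSE)
  }
  if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)) {
    stop("coordinates outside [-180,180] x [-90,90]", call. = FALSE)
  }
  xy <- project_lonlat(lon, lat, grid$projection)
  locate_xy(grid, xy[, "x"], xy[, "y"])
}

# Same assignment for already-projected coordinates (km).
locate_xy <- function(grid, x, y) {
  cs <- grid$cell_size_km
  col <- floor((x - grid$x0) / cs)
  row <- floor((y - grid$y0) / cs)
  out <- row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols
  id <- as.integer(row * grid$n_cols + col)
  id[out] <- NA_integer_
  id
}

#' Grid point occurrence records into per-cell annual counts
#'
#' Aggregates a point occurrence table to record counts per (species, year,
#' cell). Rows with missing or out-of-range coordinates, a missing or
#' non-integer year, a missing species identifier, or a location outside the
#' grid extent are dropped and tallied, never silently discarded.
#'
#' @param records A data frame of point records. Columns are matched
#'   case-insensitively against Darwin-Core-style names: species
#'   (`species`/`species_id`/`scientificName`), longitude
#'   (`decimalLongitude`/`lon`/`longitude`/`x`), latitude
#'   (`decimalLatitude`/`lat`/`latitude`/`y`), and `year` (an integer year,
#'   or a date string from which the calendar year is taken).
#' @param grid A `grid_spec`.
#' @return A list of class `gridded_occurrences` with elements:
#'   \describe{
#'     \item{counts}{data frame `(species_id, year, cell_id, n_records)`,
#'       one row per combination, `n_records >= 1`.}
#'     \item{rejections}{named integer vector of dropped-row tallies by
#'       reason (`missing_species`, `bad_coordinate`, `bad_year`,
#'       `outside_grid`).}
#'     \item{n_input}{number of input rows.}
#'   }
#'   Kept plus rejected rows always equal `n_input`, and
#'   `sum(counts$n_records)` equals the number of kept rows.
#' @export
grid_occurrences <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  records <- as.data.frame(records)
  sp  <- .find_column(records, c("species_id", "species", "scientificname"))
  lon <- .find_column(records, c("decimallongitude", "lon", "longitude", "x"))
  lat <- .find_column(records, c("decimallatitude", "lat", "latitude", "y"))
  yr  <- .find_column(records, c("year", "eventdate", "date"))

  species <- as.character(records[[sp]])
  lonv <- suppressWarnings(as.numeric(records[[lon]]))
  latv <- suppressWarnings(as.numeric(records[[lat]]))
  year <- .parse_year(records[[yr]])

  n <- nrow(records)
  rej <- c(missing_species = 0L, bad_coordinate = 0L, bad_year = 0L,
           outside_grid = 0L)

  bad_sp <- is.na(species) | !nzchar(species)
  bad_co <- !is.finite(lonv) | !is.finite(latv) |
    lonv < -180 | lonv > 180 | latv < -90 | latv > 90
  bad_yr <- is.na(year)
  # each row is counted once, under the first failing reason
  drop_sp <- bad_sp
  drop_co <- !drop_sp & bad_co
  drop_yr <- !drop_sp & !drop_co & bad_yr
  keep <- !(drop_sp | drop_co | drop_yr)
  rej["missing_species"] <- sum(drop_sp)
  rej["bad_coordinate"] <- sum(drop_co)
  rej["bad_year"] <- sum(drop_yr)

  cell <- rep(NA_integer_, n)
  if (any(keep)) cell[keep] <- locate_point(grid, lonv[keep], latv[keep])
  off <- keep & is.na(cell)
  rej["outside_grid"] <- sum(off)
  keep <- keep & !off

  if (!any(keep)) {
    counts <- data.frame(species_id = character(), year = integer(),
                         cell_id = integer(), n_records = integer(),
                         stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(
      list(n_records = rep(1L, sum(keep))),
      by = list(species_id = species[keep], year = year[keep],
                cell_id = cell[keep]),
      FUN = sum)
    counts <- agg[order(agg$species_id, agg$year, agg$cell_id), ,
                  drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(list(counts = counts, rejections = rej, n_input = n),
            class = "gridded_occurrences")
}

#' @export
print.gridded_occurrences <- function(x, ...) {
  cat(sprintf(
    "Gridded occurrences: %d records kept (%d rows), %d rejected of %d input\n",
    sum(x$counts$n_records), nrow(x$counts), sum(x$rejections), x$n_input))
  if (sum(x$rejections) > 0) {
    r <- x$rejections[x$rejections > 0]
    cat("  rejections:", paste(names(r), r, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

.find_column <- function(df, candidates) {
  hit <- match(candidates, tolower(names(df)))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) {
    stop("required column missing: one of ",
         paste(candidates, collapse = "/"), call. = FALSE)
  }
  names(df)[hit[1]]
}

# Integer years pass through; date-like strings are truncated to the
# calendar year; anything unparseable becomes NA.
.parse_year <- function(x) {
  if (is.numeric(x)) {
    y <- ifelse(is.finite(x) & x == round(x), as.integer(round(x)),
                NA_integer_)
    return(as.integer(y))
  }
  x <- as.character(x)
  y <- suppressWarnings(as.integer(x))
  dateish <- is.na(y) & grepl("^\\s*\\d{4}[-/]", x)
  y[dateish] <- suppressWarnings(
    as.integer(sub("^\\s*(\\d{4}).*$", "\\1", x[dateish])))
  frac <- !is.na(y) & !is.na(suppressWarnings(as.numeric(x))) &
    suppressWarnings(as.numeric(x)) != y
  y[frac] <- NA_integer_
  y
}
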