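# Delimited-text interchange readers/writers and the end-to-end pipeline.
# CSV with explicit headers is the canonical format; missing values are
# written as empty fields, never as 0, because 0 and "missing" are
# semantically distinct for SSEI.

#' Read a point occurrence table
#'
#' Reads Darwin-Core-style occurrence records from delimited text (CSV, or
#' TSV by extension; gzip accepted) and validates them. Rows with an
#' unparseable coordinate or year are dropped and tallied, not silently
#' discarded.
#'
#' @param path Path to the file. `.tsv`/`.txt` are read tab-separated;
#'   `.gz` is decompressed transparently.
#' @return A list with `records` (data frame with columns `species`,
#'   `decimalLongitude`, `decimalLatitude`, `year`) and `dropped` (named
#'   integer vector of per-reason drop counts).
#' @export
read_occurrences <- function(path) {
  df <- .read_delim(path)
  if (nrow(df) == 0) {
    warning("empty occurrence file: ", path, call. = FALSE)
    return(list(records = data.frame(species = character(),
                                     decimalLongitude = numeric(),
                                     decimalLatitude = numeric(),
                                     year = integer(),
                                     stringsAsFactors = FALSE),
                dropped = c(bad_coordinate = 0L, bad_year = 0L,
                            missing_species = 0L)))
  }
  sp  <- .find_column(df, c("species", "species_id", "scientificname"))
  lon <- .find_column(df, c("decimallongitude", "lon", "longitude"))
  lat <- .find_column(df, c("decimallatitude", "lat", "latitude"))
  yr  <- .find_column(df, c("year", "eventdate", "date"))
  out <- data.frame(
    species = as.character(df[[sp]]),
    decimalLongitude = suppressWarnings(as.numeric(df[[lon]])),
    decimalLatitude = suppressWarnings(as.numeric(df[[lat]])),
    year = .parse_year(df[[yr]]),
    stringsAsFactors = FALSE)
  bad_sp <- is.na(out$species) | !nzchar(out$species)
  bad_co <- !bad_sp & (!is.finite(out$decimalLongitude) |
                         !is.finite(out$decimalLatitude) |
                         abs(out$decimalLongitude) > 180 |
                         abs(out$decimalLatitude) > 90)
  bad_yr <- !bad_sp & !bad_co & is.na(out$year)
  dropped <- c(bad_coordinate = sum(bad_co), bad_year = sum(bad_yr),
               missing_species = sum(bad_sp))
  list(records = out[!(bad_sp | bad_co | bad_yr), , drop = FALSE],
       dropped = dropped)
}

#' Read range and country cell layers
#'
#' Reads the cell-layer interchange files: a range layer with columns
#' `(species_id, cell_id)` and a country layer with `(cell_id, country)`.
#' Duplicate rows are deduplicated with a warning count; a cell mapped to
#' two different countries, or a cell identifier outside the grid, is an
#' error.
#'
#' @param range_path,country_path Paths to the delimited files
#'   (`country_path` may be `NULL`).
#' @param grid Optional `grid_spec` used to validate cell identifiers.
#' @return A list with `ranges`, `countries` (data frames), and
#'   `n_duplicates` (named counts removed from each).
#' @export
read_cell_layers <- function(range_path, country_path = NULL, grid = NULL) {
  rng <- .read_delim(range_path)
  sp <- .find_column(rng, c("species_id", "species"))
  cid <- .find_column(rng, c("cell_id", "cell"))
  ranges <- data.frame(species_id = as.character(rng[[sp]]),
                       cell_id = as.integer(rng[[cid]]),
                       stringsAsFactors = FALSE)
  if (any(is.na(ranges$cell_id))) {
    stop("non-integer cell_id in range layer", call. = FALSE)
  }
  dup_r <- sum(duplicated(ranges))
  ranges <- unique(ranges)

  countries <- NULL; dup_c <- 0L
  if (!is.null(country_path)) {
    cty <- .read_delim(country_path)
    cid <- .find_column(cty, c("cell_id", "cell"))
    iso <- .find_column(cty, c("country", "iso3"))
    countries <- data.frame(cell_id = as.integer(cty[[cid]]),
                            country = as.character(cty[[iso]]),
                            stringsAsFactors = FALSE)
    dup_c <- sum(duplicated(countries))
    countries <- unique(countries)
    conf <- duplicated(countries$cell_id)
    if (any(conf)) {
      stop("conflicting country for cell(s): ",
           paste(utils::head(unique(countries$cell_id[conf]), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(grid)) {
    for (layer in list(ranges = ranges, countries = countries)) {
      if (is.null(layer)) next
      bad <- layer$cell_id < 0 | layer$cell_id >= n_cells(grid)
      if (any(bad)) {
        stop("cell identifiers outside grid extent: ",
             paste(utils::head(unique(layer$cell_id[bad]), 5),
                   collapse = ", "), call. = FALSE)
      }
    }
  }
  list(ranges = ranges, countries = countries,
       n_duplicates = c(ranges = dup_r, countries = dup_c))
}

#' Serialize and restore a grid definition
#'
#' The grid definition is stored as a small JSON key-value file alongside
#' the cell layers so that all layers can be checked for consistency.
#'
#' @param grid A `grid_spec`.
#' @param path Destination / source path.
#' @return `read_grid_spec()` returns the restored `grid_spec`.
#' @export
write_grid_spec <- function(grid, path) {
  stopifnot(inherits(grid, "grid_spec"))
  jsonlite::write_json(unclass(grid), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_spec
#' @export
read_grid_spec <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(projection = g$projection, cell_size_km = g$cell_size_km,
                 x0 = g$x0, y0 = g$y0, n_cols = as.integer(g$n_cols),
                 n_rows = as.integer(g$n_rows)),
            class = "grid_spec")
}

#' Write a data frame as canonical CSV
#'
#' Missing values become empty fields; row names are never written.
#'
#' @param df Data frame.
#' @param path Destination path.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    blank.lines.skip = TRUE)
}

#' Run the full indicator pipeline
#'
#' Chains gridding, species-level indices, annual aggregation, windowed
#' trends, and the national typology, writing every output table as CSV
#' plus a machine-readable run manifest.
#'
#' @param world Either an `ssii_world` (in-memory layers, e.g. from
#'   [make_world()] or [fig1_fixture()]) or a list of file paths:
#'   `occurrences`, `ranges`, `countries`, `grid` (a grid-spec JSON).
#' @param out_dir Output directory (created if needed); `NULL` for
#'   in-memory results only.
#' @param years Years to evaluate; default: the years present in the
#'   records.
#' @param window Trend window, default `c(2010, 2019)`.
#' @param alpha Trend significance level, default 0.01.
#' @param trend_metric Index column for trends/typology, default
#'   `"stewards_ssii"`.
#' @param ssei_opts Options forwarded to [species_ssei()].
#' @param across_taxa Passed to [annual_index_table()].
#' @return A list of class `ssii_run`: `species_indices`, `index_table`,
#'   `trends`, `typology`, `diagnostics`, and `manifest`. Written files:
#'   `species_indices.csv`, `index_table.csv`, `trends.csv`,
#'   `typology.csv`, `diagnostics.json`, `manifest.json`.
#' @export
run_pipeline <- function(world, out_dir = NULL, years = NULL,
                         window = c(2010, 2019), alpha = 0.01,
                         trend_metric = "stewards_ssii",
                         ssei_opts = list(), across_taxa = FALSE) {
  if (!inherits(world, "ssii_world")) {
    stopifnot(is.list(world), !is.null(world$occurrences),
              !is.null(world$ranges), !is.null(world$grid))
    grid <- read_grid_spec(world$grid)
    occ <- read_occurrences(world$occurrences)
    layers <- read_cell_layers(world$ranges, world$countries, grid = grid)
    taxa <- if (!is.null(world$taxa)) {
      tx <- .read_delim(world$taxa)
      data.frame(species_id = as.character(tx[[
        .find_column(tx, c("species_id", "species"))]]),
        taxon = as.character(tx[[.find_column(tx, c("taxon", "class"))]]),
        stringsAsFactors = FALSE)
    } else NULL
    world <- structure(
      list(grid = grid, countries = layers$countries,
           ranges = layers$ranges, taxa = taxa,
           occurrences = occ$records,
           config = list(inputs = world, dropped_on_read = occ$dropped)),
      class = "ssii_world")
  }
  if (is.null(world$taxa)) {
    world$taxa <- data.frame(
      species_id = unique(world$ranges$species_id), taxon = "all",
      stringsAsFactors = FALSE)
  }

  gridded <- grid_occurrences(world$occurrences, world$grid)
  if (is.null(years)) {
    years <- if (nrow(gridded$counts)) sort(unique(gridded$counts$year)) else
      window[1]:window[2]
  }
  si <- species_index_table(world$ranges, gridded, world$countries,
                            years = years, ssei_opts = ssei_opts)
  it <- annual_index_table(si, world$taxa, years = years,
                           across_taxa = across_taxa)
  tr <- trend_table(it, metric = trend_metric, window = window,
                    alpha = alpha)
  ty <- typology_table(tr)
  diagnostics <- list(
    rejections = as.list(gridded$rejections),
    n_input_records = gridded$n_input,
    out_of_range = attr(si, "out_of_range"),
    missing_taxon = attr(it, "missing_taxon"))
  manifest <- list(
    package = "ssii",
    version = as.character(utils::packageVersion("ssii")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    years = range(years), window = window, alpha = alpha,
    trend_metric = trend_metric,
    grid = unclass(world$grid),
    config = world$config)

  res <- structure(
    list(species_indices = si, index_table = it, trends = tr,
         typology = ty, diagnostics = diagnostics, manifest = manifest),
    class = "ssii_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(si, file.path(out_dir, "species_indices.csv"))
    write_table_csv(it, file.path(out_dir, "index_table.csv"))
    write_table_csv(tr, file.path(out_dir, "trends.csv"))
    write_table_csv(ty, file.path(out_dir, "typology.csv"))
    jsonlite::write_json(diagnostics, file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.ssii_run <- function(x, ...) {
  it <- x$index_table
  cat("Indicator pipeline run\n")
  cat(sprintf("  species-year index rows: %d\n", nrow(x$species_indices)))
  cat(sprintf("  annual table: %d rows (%d countries, years %d-%d)\n",
              nrow(it),
              length(unique(it$country[it$scope == "country"])),
              min(it$year), max(it$year)))
  cat(sprintf("  trends: %d series; typology: %d nations classified\n",
              nrow(x$trends), nrow(x$typology)))
  invisible(x)
}

#' @export
summary.ssii_run <- function(object, ...) {
  it <- object$index_table
  glob <- it[it$scope == "global", , drop = FALSE]
  cat("Global annual indices (by taxon):\n")
  print(glob[, c("taxon", "year", "national_ssii", "national_ssei",
                 "pct_species_recorded", "n_records")], row.names = FALSE)
  if (nrow(object$typology)) {
    cat("\nTypology quadrant percentages:\n")
    print(attr(object$typology, "quadrant_pct"))
  }
  invisible(object)
}
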