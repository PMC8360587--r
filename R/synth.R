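# Synthetic worlds for validating the index framework: toy countries tiling
# a grid, blob-shaped species ranges, and occurrence samplers with
# controllable sampling intensity, per-cell concentration, and temporal
# trends. Also exact fixtures for the two-species worked example and the
# theoretical evenness curves.

#' Generate a synthetic world (grid, countries, ranges, occurrences)
#'
#' Builds a fully synthetic but structurally realistic test world:
#' countries as contiguous axis-aligned blocks tiling the grid, species
#' ranges as connected cell blobs, and annual occurrence records drawn per
#' species-year. The per-year record total for a species is Poisson with
#' mean `lambda * (1 + trend)^t` (t = years since `years[1]`); records are
#' allocated across the species' expected cells by a symmetric
#' Dirichlet-multinomial with concentration `1/theta` per cell, so
#' `theta = 0` is the uniform-multinomial limit (even sampling) and large
#' `theta` piles records into few cells (uneven sampling). All randomness
#' derives from `seed` through a separate stream per layer, so the same
#' seed always reproduces the same world.
#'
#' @param n_countries Number of countries tiling the grid (column bands).
#' @param n_species Number of species, either a single count or a named
#'   vector of counts per taxon (names become the taxon labels).
#' @param n_cols,n_rows Grid extent in cells.
#' @param cell_size_km Cell edge length in kilometres.
#' @param range_size Mean expected-range size in cells (sizes are drawn
#'   uniformly between half and twice this, capped at the grid size).
#' @param lambda Expected records per species per year at `years[1]`.
#' @param theta Concentration parameter, `>= 0`: 0 = uniform allocation.
#' @param trend Annual multiplicative intensity trend `g` in
#'   `lambda * (1 + g)^t`.
#' @param years Integer vector of calendar years to simulate.
#' @param seed Integer random seed fixing the whole generation stream.
#' @return A list of class `ssii_world`: `grid` (a `grid_spec`),
#'   `countries` (`cell_id`, `country`), `ranges` (`species_id`,
#'   `cell_id`), `taxa` (`species_id`, `taxon`), `occurrences` (point
#'   records with Darwin-Core-style columns), and `config`.
#' @export
make_world <- function(n_countries = 3, n_species = 10,
                       n_cols = 12, n_rows = 8, cell_size_km = 110,
                       range_size = 12, lambda = 20, theta = 0,
                       trend = 0, years = 2010:2019, seed = 1) {
  stopifnot(n_countries >= 1, all(n_species >= 1), n_cols >= 1, n_rows >= 1,
            range_size >= 1, lambda > 0, theta >= 0, length(years) >= 1)
  if (range_size > n_cols * n_rows) {
    stop("infeasible config: range_size exceeds the number of grid cells",
         call. = FALSE)
  }
  grid <- build_grid(cell_size_km,
                     extent = c(0, 0, n_cols * cell_size_km,
                                n_rows * cell_size_km))
  if (is.null(names(n_species))) {
    n_species <- c(taxon1 = unname(n_species))
  }
  species_id <- sprintf("sp%03d", seq_len(sum(n_species)))
  taxa <- data.frame(species_id = species_id,
                     taxon = rep(names(n_species), n_species),
                     stringsAsFactors = FALSE)

  # countries: contiguous column bands of near-equal width
  breaks <- round(seq(0, n_cols, length.out = n_countries + 1))
  iso <- sprintf("C%02d", seq_len(n_countries))
  col_cty <- rep(iso, diff(breaks))
  all_cells <- 0:(n_cols * n_rows - 1)
  countries <- data.frame(
    cell_id = all_cells,
    country = col_cty[(all_cells %% n_cols) + 1],
    stringsAsFactors = FALSE)

  # ranges: connected blobs grown cell-by-cell from a random start
  .seed_stream(.sub_seed(seed, 1))
  ranges <- do.call(rbind, lapply(species_id, function(sp) {
    size <- min(n_cols * n_rows,
                max(1, round(stats::runif(1, range_size / 2,
                                          range_size * 2))))
    data.frame(species_id = sp,
               cell_id = .grow_blob(grid, size),
               stringsAsFactors = FALSE)
  }))

  # occurrences: per species-year totals, Dirichlet-multinomial allocation
  .seed_stream(.sub_seed(seed, 2))
  recs <- list()
  range_cells <- split(ranges$cell_id, ranges$species_id)
  for (sp in species_id) {
    cells <- range_cells[[sp]]
    for (t in seq_along(years)) {
      total <- stats::rpois(1, lambda * (1 + trend)^(t - 1))
      if (total == 0) next
      alloc <- .dirichlet_multinomial(total, length(cells), theta)
      hit <- alloc > 0
      if (!any(hit)) next
      recs[[length(recs) + 1L]] <- data.frame(
        species_id = sp, cell_id = cells[hit], n = alloc[hit],
        year = years[t], stringsAsFactors = FALSE)
    }
  }
  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(species_id = character(), cell_id = integer(), n = integer(),
               year = integer(), stringsAsFactors = FALSE)

  # expand to point records at jittered positions inside the cell
  .seed_stream(.sub_seed(seed, 3))
  idx <- rep(seq_len(nrow(recs)), recs$n)
  occ <- .cells_to_points(grid, recs$cell_id[idx])
  occurrences <- data.frame(
    species = recs$species_id[idx],
    decimalLongitude = occ[, "lon"], decimalLatitude = occ[, "lat"],
    year = recs$year[idx], stringsAsFactors = FALSE)

  structure(
    list(grid = grid, countries = countries, ranges = ranges, taxa = taxa,
         occurrences = occurrences,
         config = list(n_countries = n_countries, n_species = n_species,
                       n_cols = n_cols, n_rows = n_rows,
                       cell_size_km = cell_size_km, range_size = range_size,
                       lambda = lambda, theta = theta, trend = trend,
                       years = years, seed = seed)),
    class = "ssii_world")
}

#' @export
print.ssii_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic world: %d species, %d countries, %dx%d grid, %d records (seed %d)\n",
    nrow(x$taxa), length(unique(x$countries$country)),
    x$grid$n_cols, x$grid$n_rows, nrow(x$occurrences), x$config$seed))
  invisible(x)
}

# Deterministic sub-seed per named layer stream; stays within 32-bit range.
.sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + k * 7919L
}

.seed_stream <- function(seed) set.seed(seed)

# Grow a connected blob of `size` cells by repeatedly adding a random
# 4-neighbour of the current blob.
.grow_blob <- function(grid, size) {
  nc <- grid$n_cols; nr <- grid$n_rows
  start <- sample.int(nc * nr, 1) - 1L
  blob <- start
  frontier <- .neighbors4(start, nc, nr)
  while (length(blob) < size && length(frontier) > 0) {
    nxt <- frontier[sample.int(length(frontier), 1)]
    blob <- c(blob, nxt)
    frontier <- setdiff(unique(c(frontier, .neighbors4(nxt, nc, nr))), blob)
  }
  sort(blob)
}

.neighbors4 <- function(cell, nc, nr) {
  row <- cell %/% nc; col <- cell %% nc
  cand <- rbind(c(row - 1, col), c(row + 1, col),
                c(row, col - 1), c(row, col + 1))
  ok <- cand[, 1] >= 0 & cand[, 1] < nr & cand[, 2] >= 0 & cand[, 2] < nc
  as.integer(cand[ok, 1] * nc + cand[ok, 2])
}

# Allocate `total` records over `k` cells. theta = 0: multinomial with
# uniform probabilities; theta > 0: Dirichlet(1/theta) mixing, so larger
# theta concentrates records into fewer cells.
.dirichlet_multinomial <- function(total, k, theta) {
  if (k == 1) return(total)
  p <- if (theta == 0) {
    rep(1 / k, k)
  } else {
    g <- stats::rgamma(k, shape = 1 / theta, rate = 1)
    if (sum(g) == 0) {
      # extreme concentration: all mass on one random cell
      g[sample.int(k, 1)] <- 1
    }
    g / sum(g)
  }
  as.integer(stats::rmultinom(1, total, p))
}

# Random interior point of each cell, reported in lon/lat.
.cells_to_points <- function(grid, cell_id) {
  if (length(cell_id) == 0) {
    return(cbind(lon = numeric(0), lat = numeric(0)))
  }
  b <- cell_bounds(grid, cell_id)
  eps <- 1e-6 * grid$cell_size_km
  x <- stats::runif(length(cell_id), b[, "xmin"] + eps, b[, "xmax"] - eps)
  y <- stats::runif(length(cell_id), b[, "ymin"] + eps, b[, "ymax"] - eps)
  unproject_xy(x, y, grid$projection)
}

#' Exact fixture for the two-species worked example
#'
#' A minimal world reproducing the framework's illustrative example: a
#' focal country `AAA` and a neighbour `BBB` on a 5 x 4 grid. Species
#' `sp1` is endemic to `AAA` (6 expected cells, stewardship 1) with
#' records in 5 of them; species `sp2` has a 10-cell global range, 3 cells
#' in `AAA` (stewardship 0.3), with records in 2 of those 3. The computed
#' indices are therefore: species national SSII 5/6 and 2/3 (0.83 and
#' 0.67), Steward's species SSII 5/6 and 0.2, National SSII 0.75, and
#' Steward's national SSII 1.0333/1.3 (0.79, printed 0.8).
#'
#' @param year Calendar year stamped on the records (default 2019).
#' @return A list of class `ssii_world` with the same layers as
#'   [make_world()].
#' @export
fig1_fixture <- function(year = 2019) {
  grid <- build_grid(110, extent = c(0, 0, 5 * 110, 4 * 110))
  # columns 0-2 belong to AAA, columns 3-4 to BBB
  all_cells <- 0:(n_cells(grid) - 1)
  countries <- data.frame(
    cell_id = all_cells,
    country = ifelse(all_cells %% 5 <= 2, "AAA", "BBB"),
    stringsAsFactors = FALSE)

  # sp1: 6 cells, all in AAA (cols 0-2, rows 0-1)
  sp1_cells <- c(0, 1, 2, 5, 6, 7)
  # sp2: 10 cells, 3 in AAA (col 2, rows 1-3) and 7 in BBB
  sp2_cells <- c(7, 12, 17, 3, 4, 8, 9, 13, 14, 18)
  ranges <- rbind(
    data.frame(species_id = "sp1", cell_id = sp1_cells,
               stringsAsFactors = FALSE),
    data.frame(species_id = "sp2", cell_id = sp2_cells,
               stringsAsFactors = FALSE))

  # records: sp1 in 5 of its 6 cells; sp2 in 2 of its 3 AAA cells
  rec_cells <- list(sp1 = c(0, 1, 2, 5, 6), sp2 = c(7, 12))
  occ <- do.call(rbind, lapply(names(rec_cells), function(sp) {
    ctr <- cell_centers(grid, rec_cells[[sp]])
    ll <- unproject_xy(ctr[, "x"], ctr[, "y"], grid$projection)
    data.frame(species = sp, decimalLongitude = ll[, "lon"],
               decimalLatitude = ll[, "lat"], year = year,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(grid = grid, countries = countries, ranges = ranges,
         taxa = data.frame(species_id = c("sp1", "sp2"), taxon = "taxon1",
                           stringsAsFactors = FALSE),
         occurrences = occ,
         config = list(fixture = "two-species worked example", year = year)),
    class = "ssii_world")
}

#' Theoretical evenness-curve count vectors
#'
#' Per-cell record counts for the theoretical sampling-effectiveness
#' curves: a proportion `p` of the sampled cells holds a single record and
#' the remainder holds `v` records each. Sweeping `p` from 0 to 1 for
#' `v` in \{1, 2, 10, 100, 1000\} traces how effectiveness degrades as
#' redundant sampling concentrates.
#'
#' @param n_cells Number of sampled cells (`>= 2`).
#' @param p Proportion of cells with a single record, in `[0, 1]`.
#' @param v Record count in the remaining cells.
#' @return Integer vector of length `n_cells`: `round(p * n_cells)` ones
#'   followed by `v`s.
#' @export
figD_counts <- function(n_cells, p, v) {
  stopifnot(n_cells >= 2, p >= 0, p <= 1, v >= 1)
  k <- round(p * n_cells)
  c(rep(1L, k), rep(as.integer(v), n_cells - k))
}

#' Synthetic annual index series with a linear trend
#'
#' Generates `value = base + slope * t + noise` over a span of years
#' (t = 0, 1, ...), for exercising the windowed trend machinery.
#'
#' @param base Intercept at the first year.
#' @param slope Per-year change.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param years Integer vector of years (length `>= 3`).
#' @param seed Optional seed for the noise draw.
#' @return A data frame `(year, value)`.
#' @export
trend_scenario <- function(base, slope, noise_sd, years = 2010:2019,
                           seed = NULL) {
  stopifnot(length(years) >= 3)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_along(years) - 1
  data.frame(year = years,
             value = base + slope * t + stats::rnorm(length(years), 0,
                                                     noise_sd))
}
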