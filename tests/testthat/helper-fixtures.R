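# Shared helpers: tiny grids, brute-force oracles, and world shortcuts.

# 6 x 3 grid of 110-km cells at the projected origin.
toy_grid <- function(cell = 110, ncols = 6, nrows = 3) {
  build_grid(cell, extent = c(0, 0, ncols * cell, nrows * cell))
}

# Exhaustive rectangle-containment point location: scans every cell's
# half-open bounding box. Independent of the arithmetic in locate_point().
brute_locate <- function(grid, x, y) {
  ids <- 0:(n_cells(grid) - 1)
  b <- cell_bounds(grid, ids)
  vapply(seq_along(x), function(i) {
    hit <- which(x[i] >= b[, "xmin"] & x[i] < b[, "xmax"] &
                   y[i] >= b[, "ymin"] & y[i] < b[, "ymax"])
    if (length(hit) == 1) ids[hit] else NA_integer_
  }, integer(1))
}

# Direct entropy-based evenness, written independently of species_ssei().
brute_ssei <- function(counts) {
  p <- counts / sum(counts)
  if (length(counts) < 2) return(NA_real_)
  -sum(p * log(p)) / log(length(counts))
}

# A small random world for property tests.
small_world <- function(seed, ...) {
  make_world(n_countries = 3, n_species = 4, n_cols = 8, n_rows = 6,
             range_size = 8, lambda = 10, years = 2017:2019, seed = seed,
             ...)
}
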