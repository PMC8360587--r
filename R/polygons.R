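# Conversion of polygon layers (species ranges, country boundaries) to grid
# cells. Polygons are simple rings in geographic coordinates; cell overlap
# areas are computed in projected space by clipping each ring to the cell
# rectangle (Sutherland-Hodgman), which is exact for the axis-aligned cells
# used here. Rings with holes are not supported.

#' Rasterize polygon features to grid cells
#'
#' Converts polygon features (e.g. expert range maps) to sets of grid cells
#' under a selectable inclusion rule.
#'
#' @param polygons Either a list of features, each a two-column matrix (or
#'   list of matrices for multi-part features) of `lon`, `lat` ring
#'   vertices, or a path to a GeoJSON file of Polygon/MultiPolygon features
#'   (outer rings only). Feature names are kept if present.
#' @param grid A `grid_spec`.
#' @param rule Inclusion rule: `"any-overlap"` (any positive intersection
#'   area), `"center-in"` (cell centre inside the polygon), or
#'   `"majority-area"` (more than half the cell area covered).
#' @return A named list, one integer vector of cell identifiers per feature.
#' @export
rasterize_polygons <- function(polygons, grid,
                               rule = c("any-overlap", "center-in",
                                        "majority-area")) {
  rule <- match.arg(rule)
  stopifnot(inherits(grid, "grid_spec"))
  feats <- .as_features(polygons, grid$projection)
  out <- vector("list", length(feats))
  names(out) <- names(feats)
  for (i in seq_along(feats)) {
    rings <- feats[[i]]
    if (length(rings) == 0 || any(!vapply(rings, .valid_ring, logical(1)))) {
      stop(sprintf("invalid or empty geometry in feature %d", i),
           call. = FALSE)
    }
    out[[i]] <- .rasterize_rings(rings, grid, rule)
  }
  out
}

#' Assign grid cells to countries
#'
#' Builds the exclusive cell-to-country layer used for national index
#' restriction and stewardship weights. Each cell belongs to at most one
#' country: with polygon input, to the country with the largest overlapped
#' area (ties broken by lexicographically smallest ISO3 code); cells
#' overlapped by no country are `"UNASSIGNED"`. With `fractional = TRUE`
#' the per-country area fractions are returned instead of an exclusive
#' assignment.
#'
#' @param countries Either a data frame with columns `cell_id` and `country`
#'   (explicit tabular assignment), or polygon features as in
#'   [rasterize_polygons()] named by ISO3 code.
#' @param grid A `grid_spec`.
#' @param fractional Logical; polygon input only. If `TRUE`, return a data
#'   frame `(cell_id, country, fraction)` of area fractions instead of the
#'   exclusive majority-area assignment.
#' @return A data frame `(cell_id, country)` with at most one row per cell
#'   (or the fractional table described above).
#' @export
assign_cells_to_countries <- function(countries, grid, fractional = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.data.frame(countries)) {
    df <- countries
    cid <- .find_column(df, c("cell_id", "cell"))
    cty <- .find_column(df, c("country", "iso3"))
    out <- data.frame(cell_id = as.integer(df[[cid]]),
                      country = as.character(df[[cty]]),
                      stringsAsFactors = FALSE)
    if (any(is.na(out$cell_id)) ||
        any(out$cell_id < 0 | out$cell_id >= n_cells(grid))) {
      stop("tabular country layer contains cell identifiers outside the grid",
           call. = FALSE)
    }
    out <- unique(out)
    dup <- duplicated(out$cell_id)
    if (any(dup)) {
      stop("conflicting country assignment for cell(s): ",
           paste(utils::head(unique(out$cell_id[dup]), 5), collapse = ", "),
           call. = FALSE)
    }
    return(out[order(out$cell_id), , drop = FALSE])
  }

  feats <- .as_features(countries, grid$projection)
  if (is.null(names(feats)) || any(!nzchar(names(feats)))) {
    stop("polygon country layer must be named by ISO3 code", call. = FALSE)
  }
  cell_area <- grid$cell_size_km^2
  frac <- list()
  for (iso in names(feats)) {
    areas <- .ring_cell_areas(feats[[iso]], grid)
    if (nrow(areas) > 0) {
      frac[[length(frac) + 1L]] <- data.frame(
        cell_id = areas$cell_id, country = iso,
        fraction = areas$area / cell_area, stringsAsFactors = FALSE)
    }
  }
  frac <- if (length(frac)) do.call(rbind, frac) else
    data.frame(cell_id = integer(), country = character(),
               fraction = numeric(), stringsAsFactors = FALSE)
  if (fractional) {
    return(frac[order(frac$cell_id, frac$country), , drop = FALSE])
  }
  if (nrow(frac) == 0) {
    return(data.frame(cell_id = integer(), country = character(),
                      stringsAsFactors = FALSE))
  }
  # majority area, ties to the lexicographically smallest ISO3; fractions
  # are rounded so floating-point noise in the clipped areas cannot decide
  # a genuine tie
  frac <- frac[order(frac$cell_id, -round(frac$fraction, 9), frac$country), ,
               drop = FALSE]
  win <- frac[!duplicated(frac$cell_id), c("cell_id", "country")]
  rownames(win) <- NULL
  win
}

# ---- internal geometry ------------------------------------------------------

.valid_ring <- function(m) {
  is.matrix(m) && ncol(m) == 2 && nrow(m) >= 3 && all(is.finite(m))
}

# Normalize polygon input to a list of features, each a list of projected
# rings (two-column matrices in km).
.as_features <- function(polygons, projection) {
  if (is.character(polygons) && length(polygons) == 1) {
    polygons <- read_geojson_polygons(polygons)
  }
  if (!is.list(polygons)) stop("unsupported polygon input", call. = FALSE)
  lapply(polygons, function(f) {
    rings <- if (is.matrix(f)) list(f) else f
    lapply(rings, function(r) {
      r <- as.matrix(r)
      project_lonlat(r[, 1], r[, 2], projection)
    })
  })
}

#' Read Polygon/MultiPolygon features from a GeoJSON file
#'
#' Minimal GeoJSON reader for toy geometries: outer rings only (holes are
#' rejected). Feature names are taken from a `name` or `iso3` property when
#' present.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @return A named list of features, each a list of two-column `lon`, `lat`
#'   ring matrices, suitable for [rasterize_polygons()].
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else
    list(gj)
  out <- list(); nm <- character()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    ring_of <- function(r) {
      do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    }
    rings <- switch(
      geom$type,
      Polygon = {
        if (length(geom$coordinates) > 1)
          stop("polygon holes are not supported", call. = FALSE)
        list(ring_of(geom$coordinates[[1]]))
      },
      MultiPolygon = lapply(geom$coordinates, function(poly) {
        if (length(poly) > 1)
          stop("polygon holes are not supported", call. = FALSE)
        ring_of(poly[[1]])
      }),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    prop <- f$properties
    nm <- c(nm, if (!is.null(prop$iso3)) prop$iso3 else
      if (!is.null(prop$name)) prop$name else "")
    out[[length(out) + 1L]] <- rings
  }
  if (any(nzchar(nm))) names(out) <- nm
  out
}

# Signed area (shoelace); positive for counter-clockwise rings.
.ring_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Clip a ring to an axis-aligned rectangle (Sutherland-Hodgman). Returns a
# matrix of vertices (possibly empty).
.clip_ring_rect <- function(m, xmin, ymin, xmax, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  m <- clip_edge(m, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  m <- clip_edge(m, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  m <- clip_edge(m, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  m <- clip_edge(m, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  m
}

# Even-odd point-in-polygon over a set of rings.
.point_in_rings <- function(x, y, rings) {
  inside <- FALSE
  for (m in rings) {
    px <- m[, 1]; py <- m[, 2]
    n <- nrow(m)
    j <- c(n, seq_len(n - 1))
    crosses <- ((py > y) != (py[j] > y)) &
      (x < (px[j] - px) * (y - py) / (py[j] - py) + px)
    if (sum(crosses) %% 2 == 1) inside <- !inside
  }
  inside
}

# Per-cell intersection area of a multi-ring feature, restricted to cells
# intersecting the feature bbox. Returns data.frame(cell_id, area).
.ring_cell_areas <- function(rings, grid) {
  cs <- grid$cell_size_km
  allv <- do.call(rbind, rings)
  c0 <- max(0L, floor((min(allv[, 1]) - grid$x0) / cs))
  c1 <- min(grid$n_cols - 1L, floor((max(allv[, 1]) - grid$x0) / cs + 1e-12))
  r0 <- max(0L, floor((min(allv[, 2]) - grid$y0) / cs))
  r1 <- min(grid$n_rows - 1L, floor((max(allv[, 2]) - grid$y0) / cs + 1e-12))
  if (c1 < c0 || r1 < r0) {
    return(data.frame(cell_id = integer(), area = numeric()))
  }
  ids <- areas <- numeric(0)
  for (row in r0:r1) {
    for (col in c0:c1) {
      xmin <- grid$x0 + col * cs; ymin <- grid$y0 + row * cs
      a <- 0
      for (m in rings) {
        cl <- .clip_ring_rect(m, xmin, ymin, xmin + cs, ymin + cs)
        if (nrow(cl) >= 3) a <- a + abs(.ring_area(cl))
      }
      if (a > 0) {
        ids <- c(ids, row * grid$n_cols + col)
        areas <- c(areas, a)
      }
    }
  }
  data.frame(cell_id = as.integer(ids), area = areas)
}

.rasterize_rings <- function(rings, grid, rule) {
  cell_area <- grid$cell_size_km^2
  rel_tol <- 1e-9 * cell_area
  if (rule == "center-in") {
    areas <- .ring_cell_areas(rings, grid)
    cand <- areas$cell_id[areas$area > rel_tol]
    ctr <- cell_centers(grid, cand)
    keep <- vapply(seq_along(cand), function(i) {
      .point_in_rings(ctr[i, "x"], ctr[i, "y"], rings)
    }, logical(1))
    return(sort(cand[keep]))
  }
  areas <- .ring_cell_areas(rings, grid)
  thr <- if (rule == "majority-area") cell_area / 2 else rel_tol
  sort(areas$cell_id[areas$area > thr])
}
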