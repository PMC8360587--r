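# Species-level coverage and sampling-effectiveness indices.
#
# SSII (Species Status Information Index): the proportion of a species'
# expected range cells holding at least one occurrence record in a given
# year. National SSII restricts the expected range to the cells assigned to
# one country; Steward's SSII multiplies national coverage by the national
# stewardship weight (the fraction of the global range held by the country),
# so that summing Steward's SSII over countries recovers the global SSII.
#
# SSEI (Species Sampling Effectiveness Index): Shannon entropy of the
# per-cell distribution of records, normalized by the entropy of the ideal
# uniform distribution; 1 = perfectly even sampling, values near 0 =
# records piled into few cells.

#' Species-level coverage (SSII) from cell sets
#'
#' The proportion of expected range cells that hold data:
#' `|sampled| / |expected|`. Sampled cells outside the expected range are
#' ignored (indices are defined relative to the expected range).
#'
#' @param expected_cells Integer vector of expected range cell identifiers
#'   (non-empty).
#' @param sampled_cells Integer vector of cells with at least one record.
#' @return Coverage fraction in `[0, 1]`.
#' @examples
#' species_coverage(1:6, 1:5)  # 0.833...
#' species_coverage(1:3, 1:2)  # 0.666...
#' @export
species_coverage <- function(expected_cells, sampled_cells) {
  expected_cells <- unique(expected_cells)
  if (length(expected_cells) == 0) {
    stop("expected range is empty: coverage is undefined", call. = FALSE)
  }
  length(intersect(unique(sampled_cells), expected_cells)) /
    length(expected_cells)
}

#' National stewardship weights for one species
#'
#' The stewardship a country holds for a species is the fraction of the
#' species' global expected range falling inside that country (1 for a
#' country endemic). Weights over all countries, including the
#' `"UNASSIGNED"` remainder, sum to 1.
#'
#' @param expected_cells Integer vector of the species' expected range cells.
#' @param assignment Cell-to-country data frame `(cell_id, country)` from
#'   [assign_cells_to_countries()]; expected cells absent from it fall under
#'   `"UNASSIGNED"`.
#' @return A data frame `(country, weight)`; weights sum to 1.
#' @export
stewardship_weights <- function(expected_cells, assignment) {
  expected_cells <- unique(as.integer(expected_cells))
  if (length(expected_cells) == 0) {
    stop("expected range is empty: stewardship is undefined", call. = FALSE)
  }
  country <- assignment$country[match(expected_cells, assignment$cell_id)]
  country[is.na(country)] <- "UNASSIGNED"
  tab <- table(country)
  out <- data.frame(country = names(tab),
                    weight = as.numeric(tab) / length(expected_cells),
                    stringsAsFactors = FALSE)
  out[order(out$country), , drop = FALSE]
}

#' Steward's species-level SSII
#'
#' Adjusts a species' national coverage by the country's stewardship of the
#' species: the product `national_coverage * weight`. Summed over all the
#' countries where the species is expected, this recovers the species'
#' global SSII.
#'
#' @param national_coverage National SSII (fraction in `[0, 1]`).
#' @param weight National stewardship weight (fraction in `[0, 1]`).
#' @return The product, a fraction in `[0, 1]`.
#' @export
stewards_species_ssii <- function(national_coverage, weight) {
  stopifnot(all(national_coverage >= 0 & national_coverage <= 1, na.rm = TRUE),
            all(weight >= 0 & weight <= 1, na.rm = TRUE))
  national_coverage * weight
}

#' Species global SSII for one year
#'
#' Coverage across the species' full expected range, counting cells with at
#' least one record of the species in the given year, without regard to
#' national boundaries.
#'
#' @param expected_cells Integer vector of expected range cells.
#' @param gridded A `gridded_occurrences` object (or its `counts` data
#'   frame).
#' @param species_id,year The species and calendar year to evaluate.
#' @return Coverage fraction in `[0, 1]`.
#' @export
species_global_ssii <- function(expected_cells, gridded, species_id, year) {
  counts <- if (inherits(gridded, "gridded_occurrences")) gridded$counts else
    gridded
  sampled <- counts$cell_id[counts$species_id == species_id &
                              counts$year == year]
  species_coverage(expected_cells, sampled)
}

#' Species sampling effectiveness (SSEI)
#'
#' Normalized Shannon entropy of the per-cell record distribution:
#' `H = -sum(p_i * log(p_i))` with `p_i = r_i / R`, divided by the entropy
#' of the ideal uniform distribution. With the default denominator
#' (`"sampled"`), the ideal spreads the records evenly over the `n` sampled
#' cells (`log(n)`); with `"expected"` it spreads them over the full
#' expected range (`log(n_expected)`). A single sampled cell leaves the
#' default normalization undefined (0/0) and returns `NA` so the species
#' drops out of downstream means; `single_cell` can substitute 0 or 1
#' instead.
#'
#' @param record_counts Positive integer record counts, one per sampled
#'   cell.
#' @param denominator `"sampled"` (default) or `"expected"`.
#' @param n_expected Expected range size; required when
#'   `denominator = "expected"`.
#' @param single_cell Convention when only one cell is sampled (default
#'   normalization only): `"missing"` (default), `"zero"`, or `"one"`.
#' @return SSEI in `[0, 1]`, or `NA` where the convention says missing. The
#'   value is 1 exactly when counts are uniform, is invariant under scaling
#'   all counts by a constant, and decreases as records concentrate.
#' @examples
#' species_ssei(c(1, 1, 1))     # 1
#' species_ssei(c(10, 10, 10))  # 1 (scale-invariant)
#' species_ssei(c(1, 1, 1, 1000))  # far below 1
#' @export
species_ssei <- function(record_counts,
                         denominator = c("sampled", "expected"),
                         n_expected = NULL,
                         single_cell = c("missing", "zero", "one")) {
  denominator <- match.arg(denominator)
  single_cell <- match.arg(single_cell)
  if (length(record_counts) == 0) return(NA_real_)
  if (any(!is.finite(record_counts) | record_counts <= 0)) {
    stop("record counts must be positive", call. = FALSE)
  }
  n <- length(record_counts)
  p <- record_counts / sum(record_counts)
  H <- -sum(p * log(p))
  if (denominator == "expected") {
    if (is.null(n_expected) || n_expected < 1) {
      stop("`n_expected` is required for denominator = \"expected\"",
           call. = FALSE)
    }
    if (n_expected == 1) return(1)
    return(H / log(n_expected))
  }
  if (n == 1) {
    return(switch(single_cell, missing = NA_real_, zero = 0, one = 1))
  }
  H / log(n)
}

#' Per-species, per-year index bundle for one scope
#'
#' Computes the full set of species-level quantities for one species, one
#' year, and one scope (global, or national when `country` is given):
#' expected and sampled cell counts, record total, SSII, Steward's SSII
#' (national scope), and SSEI. Records of the species outside its expected
#' range are excluded.
#'
#' @param expected_cells The species' global expected range cells.
#' @param gridded A `gridded_occurrences` object (or its `counts` frame).
#' @param species_id,year Species and calendar year.
#' @param assignment Cell-to-country table, required for national scope.
#' @param country ISO3 code for national scope; `NULL` for global.
#' @param ssei_opts List of options passed to [species_ssei()]
#'   (`denominator`, `single_cell`).
#' @return A one-row data frame with columns `species_id`, `scope`,
#'   `country`, `year`, `n_expected`, `n_sampled`, `n_records`, `ssii`,
#'   `stewards_ssii`, `ssei`, and `weight` (the national stewardship
#'   weight; `NA` at global scope).
#' @export
species_year_indices <- function(expected_cells, gridded, species_id, year,
                                 assignment = NULL, country = NULL,
                                 ssei_opts = list()) {
  counts <- if (inherits(gridded, "gridded_occurrences")) gridded$counts else
    gridded
  expected_cells <- unique(as.integer(expected_cells))
  if (length(expected_cells) == 0) {
    stop("expected range is empty", call. = FALSE)
  }
  weight <- NA_real_
  scope_cells <- expected_cells
  if (!is.null(country)) {
    if (is.null(assignment)) {
      stop("`assignment` is required for national scope", call. = FALSE)
    }
    if (!country %in% assignment$country) {
      stop("unknown country code: ", country, call. = FALSE)
    }
    in_country <- assignment$cell_id[assignment$country == country]
    scope_cells <- intersect(expected_cells, in_country)
    weight <- length(scope_cells) / length(expected_cells)
  }
  sub <- counts[counts$species_id == species_id & counts$year == year &
                  counts$cell_id %in% scope_cells, , drop = FALSE]
  n_exp <- length(scope_cells)
  ssii <- if (n_exp == 0) NA_real_ else nrow(sub) / n_exp
  ssei <- if (nrow(sub) == 0) NA_real_ else
    do.call(species_ssei, c(list(record_counts = sub$n_records,
                                 n_expected = n_exp), ssei_opts))
  data.frame(
    species_id = species_id,
    scope = if (is.null(country)) "global" else "country",
    country = if (is.null(country)) NA_character_ else country,
    year = as.integer(year),
    n_expected = n_exp,
    n_sampled = nrow(sub),
    n_records = if (nrow(sub)) sum(sub$n_records) else 0L,
    ssii = ssii,
    stewards_ssii = if (is.null(country)) NA_real_ else ssii * weight,
    ssei = ssei,
    weight = weight,
    stringsAsFactors = FALSE)
}

#' Species-level index table across species, years, and scopes
#'
#' Evaluates SSII, Steward's SSII, and SSEI for every species in the range
#' layer, every requested year, at global scope and within every country
#' where the species is expected. Species with zero records in a year still
#' appear, with coverage 0 and SSEI missing, so national means can fall
#' when sampling stops. Records of a species outside its expected range are
#' excluded from its indices and tallied in the `out_of_range` attribute.
#'
#' @param ranges Range layer: data frame `(species_id, cell_id)` of expected
#'   range cells.
#' @param gridded A `gridded_occurrences` object (or its `counts` frame).
#' @param assignment Cell-to-country table `(cell_id, country)`; may be
#'   `NULL` for a global-only table.
#' @param years Integer vector of calendar years to evaluate.
#' @param ssei_opts Options forwarded to [species_ssei()].
#' @return A data frame with the columns of [species_year_indices()]
#'   (including the per-country stewardship `weight`), one row per species
#'   x year x scope; expected range cells under no country appear as an
#'   `"UNASSIGNED"` pseudo-country so the national rows always partition
#'   the range. Attribute `out_of_range` holds a data frame of per-species
#'   out-of-range record tallies.
#' @export
species_index_table <- function(ranges, gridded, assignment = NULL,
                                years, ssei_opts = list()) {
  counts <- if (inherits(gridded, "gridded_occurrences")) gridded$counts else
    gridded
  ranges <- unique(data.frame(species_id = as.character(ranges$species_id),
                              cell_id = as.integer(ranges$cell_id),
                              stringsAsFactors = FALSE))
  species <- sort(unique(ranges$species_id))
  years <- sort(unique(as.integer(years)))
  range_cells <- split(ranges$cell_id, ranges$species_id)

  # out-of-range diagnostics: records of a known species outside its range
  oor <- counts[counts$species_id %in% species, , drop = FALSE]
  if (nrow(oor)) {
    in_range <- mapply(function(sp, cl) cl %in% range_cells[[sp]],
                       oor$species_id, oor$cell_id)
    oor <- oor[!in_range, , drop = FALSE]
  }
  oor_tab <- if (nrow(oor)) {
    stats::aggregate(list(n_records = oor$n_records),
                     by = list(species_id = oor$species_id), FUN = sum)
  } else {
    data.frame(species_id = character(), n_records = integer(),
               stringsAsFactors = FALSE)
  }

  cty_cells <- if (!is.null(assignment)) {
    split(assignment$cell_id, assignment$country)
  } else list()

  rows <- vector("list", 0)
  for (sp in species) {
    exp_cells <- range_cells[[sp]]
    n_exp <- length(exp_cells)
    # pre-split this species' in-range counts by year
    spc <- counts[counts$species_id == sp &
                    counts$cell_id %in% exp_cells, , drop = FALSE]
    # national partition of the range (computed once per species)
    parts <- list()
    if (!is.null(assignment)) {
      for (cty in names(cty_cells)) {
        sub <- intersect(exp_cells, cty_cells[[cty]])
        if (length(sub)) parts[[cty]] <- sub
      }
      # range cells under no country: an UNASSIGNED pseudo-country, so the
      # national partition always covers the range and Steward's SSII sums
      # to the global SSII exactly
      left <- setdiff(exp_cells, unlist(parts, use.names = FALSE))
      if (length(left) && is.null(parts[["UNASSIGNED"]])) {
        parts[["UNASSIGNED"]] <- left
      }
    }
    for (yr in years) {
      yc <- spc[spc$year == yr, , drop = FALSE]
      rows[[length(rows) + 1L]] <- .index_row(
        sp, "global", NA_character_, yr, n_exp, yc, NA_real_, ssei_opts)
      for (cty in names(parts)) {
        sub <- parts[[cty]]
        ycc <- yc[yc$cell_id %in% sub, , drop = FALSE]
        rows[[length(rows) + 1L]] <- .index_row(
          sp, "country", cty, yr, length(sub), ycc,
          length(sub) / n_exp, ssei_opts)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "out_of_range") <- oor_tab
  out
}

.index_row <- function(sp, scope, country, year, n_exp, yc, weight,
                       ssei_opts) {
  ssii <- nrow(yc) / n_exp
  ssei <- if (nrow(yc) == 0) NA_real_ else
    do.call(species_ssei, c(list(record_counts = yc$n_records,
                                 n_expected = n_exp), ssei_opts))
  data.frame(
    species_id = sp, scope = scope, country = country,
    year = as.integer(year), n_expected = n_exp, n_sampled = nrow(yc),
    n_records = if (nrow(yc)) sum(yc$n_records) else 0L,
    ssii = ssii,
    stewards_ssii = if (scope == "country") ssii * weight else NA_real_,
    ssei = ssei,
    weight = weight, stringsAsFactors = FALSE)
}
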