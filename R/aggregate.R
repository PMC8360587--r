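# Aggregation of species-level indices to national/global annual series,
# decadal trend estimation, national typology, and the stewardship-
# preference diagnostic.

#' National SSII: mean coverage across expected species
#'
#' Unweighted arithmetic mean of national coverages over all species
#' expected in the country, including species with zero records (coverage
#' 0) — otherwise the index could not fall when sampling stops.
#'
#' @param coverages National coverage fractions, one per expected species.
#' @return The mean, or `NA` for an empty species set.
#' @examples
#' national_ssii(c(5 / 6, 2 / 3))  # 0.75
#' @export
national_ssii <- function(coverages) {
  coverages <- coverages[!is.na(coverages)]
  if (length(coverages) == 0) return(NA_real_)
  mean(coverages)
}

#' Steward's national SSII: stewardship-weighted mean coverage
#'
#' Weighted mean of national coverages with each species' national
#' stewardship as its weight: `sum(w * c) / sum(w)`. Equal weights reduce
#' it to the unweighted mean.
#'
#' @param coverages National coverage fractions, one per expected species.
#' @param weights National stewardship weights (non-negative, not all 0).
#' @return The weighted mean, or `NA` when no species has positive weight.
#' @examples
#' stewards_national_ssii(c(5 / 6, 2 / 3), c(1, 0.3))  # 0.7949 -> 0.8 (1 d.p.)
#' @export
stewards_national_ssii <- function(coverages, weights) {
  ok <- !is.na(coverages) & !is.na(weights)
  coverages <- coverages[ok]; weights <- weights[ok]
  if (length(weights) == 0 || any(weights < 0)) {
    if (any(weights < 0)) stop("negative stewardship weight", call. = FALSE)
    return(NA_real_)
  }
  if (sum(weights) == 0) return(NA_real_)
  sum(weights * coverages) / sum(weights)
}

#' National SSEI: mean sampling effectiveness across expected species
#'
#' Unweighted mean of the available per-species national SSEI values;
#' species whose SSEI is missing (fewer than two sampled cells under the
#' default convention) are excluded, and the national value is missing when
#' no species has one.
#'
#' @param ssei_values Per-species SSEI values, `NA` for missing.
#' @param weights Optional stewardship weights for a Steward's SSEI
#'   (weighted mean over the non-missing values).
#' @return The mean (weighted if `weights` given), or `NA`.
#' @export
national_ssei <- function(ssei_values, weights = NULL) {
  ok <- !is.na(ssei_values)
  if (!any(ok)) return(NA_real_)
  if (is.null(weights)) return(mean(ssei_values[ok]))
  w <- weights[ok]
  if (sum(w) == 0) return(NA_real_)
  sum(w * ssei_values[ok]) / sum(w)
}

#' Percentage of expected species recorded
#'
#' Of the species expected in a scope, the share with at least one record.
#'
#' @param expected_species Character vector of expected species.
#' @param recorded_species Character vector of species with records
#'   (intersected with `expected_species`).
#' @return Percentage in `[0, 100]`, or `NA` for an empty expected set.
#' @export
pct_species_recorded <- function(expected_species, recorded_species) {
  expected_species <- unique(expected_species)
  if (length(expected_species) == 0) return(NA_real_)
  100 * length(intersect(unique(recorded_species), expected_species)) /
    length(expected_species)
}

#' Annual national/global index table
#'
#' Aggregates the species-level index table to one row per scope x taxon x
#' year: National (or Global) SSII as the mean coverage across expected
#' species, Steward's national SSII as the stewardship-weighted mean,
#' National SSEI as the mean over available species values, the percentage
#' of expected species recorded, record totals, and expected species
#' counts. Global-scope rows aggregate across full species ranges without
#' national restriction. Optional `"all"` taxon rows average across taxa.
#'
#' @param species_indices Output of [species_index_table()].
#' @param taxa Data frame `(species_id, taxon)` mapping species to
#'   taxonomic groups; species without a taxon are excluded and listed in
#'   the `missing_taxon` attribute.
#' @param years Years to tabulate; defaults to the years present.
#' @param across_taxa If `TRUE`, add rows with taxon `"all"` per scope-year.
#' @param across_taxa_method `"taxon_mean"` (mean of the taxon-level index
#'   values, the default) or `"pooled"` (all species pooled).
#' @return An `IndexTable` data frame with columns `scope`, `country`,
#'   `taxon`, `year`, `national_ssii`, `stewards_ssii`, `national_ssei`,
#'   `pct_species_recorded`, `n_records`, `n_species_expected`.
#' @export
annual_index_table <- function(species_indices, taxa, years = NULL,
                               across_taxa = FALSE,
                               across_taxa_method = c("taxon_mean",
                                                      "pooled")) {
  across_taxa_method <- match.arg(across_taxa_method)
  si <- species_indices
  if (is.null(years)) years <- sort(unique(si$year))
  taxa <- unique(data.frame(species_id = as.character(taxa$species_id),
                            taxon = as.character(taxa$taxon),
                            stringsAsFactors = FALSE))
  missing_taxon <- setdiff(unique(si$species_id), taxa$species_id)
  si$taxon <- taxa$taxon[match(si$species_id, taxa$species_id)]
  si <- si[!is.na(si$taxon) & si$year %in% years, , drop = FALSE]

  key_levels <- unique(si[, c("scope", "country")])
  rows <- list()
  for (k in seq_len(nrow(key_levels))) {
    scope <- key_levels$scope[k]; cty <- key_levels$country[k]
    sel <- si$scope == scope &
      (is.na(cty) | (!is.na(si$country) & si$country == cty))
    sub_all <- si[sel, , drop = FALSE]
    taxa_here <- sort(unique(sub_all$taxon))
    for (tx in taxa_here) {
      for (yr in years) {
        sub <- sub_all[sub_all$taxon == tx & sub_all$year == yr, ,
                       drop = FALSE]
        if (nrow(sub) == 0) next
        rows[[length(rows) + 1L]] <- .agg_row(scope, cty, tx, yr, sub)
      }
    }
    if (across_taxa && length(taxa_here) > 1) {
      for (yr in years) {
        sub <- sub_all[sub_all$year == yr, , drop = FALSE]
        if (nrow(sub) == 0) next
        if (across_taxa_method == "pooled") {
          rows[[length(rows) + 1L]] <- .agg_row(scope, cty, "all", yr, sub)
        } else {
          per_tx <- lapply(split(sub, sub$taxon),
                           function(s) .agg_row(scope, cty, "all", yr, s))
          per_tx <- do.call(rbind, per_tx)
          rows[[length(rows) + 1L]] <- data.frame(
            scope = scope, country = cty, taxon = "all", year = yr,
            national_ssii = mean(per_tx$national_ssii, na.rm = TRUE),
            stewards_ssii = .na_mean(per_tx$stewards_ssii),
            national_ssei = .na_mean(per_tx$national_ssei),
            pct_species_recorded = mean(per_tx$pct_species_recorded,
                                        na.rm = TRUE),
            n_records = sum(per_tx$n_records),
            n_species_expected = sum(per_tx$n_species_expected),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$scope, out$country, out$taxon, out$year), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_taxon") <- missing_taxon
  out
}

.na_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

.agg_row <- function(scope, cty, tx, yr, sub) {
  data.frame(
    scope = scope, country = cty, taxon = tx, year = yr,
    national_ssii = national_ssii(sub$ssii),
    stewards_ssii = if (scope == "country") {
      stewards_national_ssii(sub$ssii, sub$weight)
    } else NA_real_,
    national_ssei = national_ssei(sub$ssei),
    pct_species_recorded = pct_species_recorded(
      sub$species_id, sub$species_id[sub$n_records > 0]),
    n_records = sum(sub$n_records),
    n_species_expected = length(unique(sub$species_id)),
    stringsAsFactors = FALSE)
}

#' Decadal (windowed) trend in an annual index series
#'
#' Ordinary least-squares regression of the index on year over a window,
#' with a two-sided t-test on the slope. The series is classified
#' `"increasing"` if the slope is positive and significant at `alpha`,
#' `"decreasing"` if negative and significant, `"none"` otherwise. A
#' rank-based Mann-Kendall option is provided.
#'
#' @param years,values The annual series (missing values dropped).
#' @param window Inclusive year window `c(start, end)`; default `c(2010,
#'   2019)`, the previous decade.
#' @param alpha Significance level; default 0.01.
#' @param method `"ols"` (default) or `"mann-kendall"` (Kendall rank
#'   correlation test; the reported slope is then the Theil-Sen estimate).
#' @return A list of class `trend_result`: `window`, `n`, `mean_value`,
#'   `slope` (per year), `p_value`, `trend_class`, and `insufficient_data`
#'   (`TRUE` when fewer than 3 values fall in the window, in which case the
#'   class is `"none"` with missing slope and p).
#' @export
decadal_trend <- function(years, values, window = c(2010, 2019),
                          alpha = 0.01, method = c("ols", "mann-kendall")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  ok <- !is.na(years) & !is.na(values) &
    years >= window[1] & years <= window[2]
  yr <- years[ok]; v <- values[ok]
  res <- list(window = window, n = length(v),
              mean_value = if (length(v)) mean(v) else NA_real_,
              slope = NA_real_, p_value = NA_real_,
              trend_class = "none", insufficient_data = FALSE)
  if (length(v) < 3 || length(unique(yr)) < 3) {
    res$insufficient_data <- TRUE
    class(res) <- "trend_result"
    return(res)
  }
  if (stats::var(v) == 0) {
    res$slope <- 0
    res$p_value <- 1
    class(res) <- "trend_result"
    return(res)
  }
  if (method == "ols") {
    fit <- stats::lm(v ~ yr)
    sm <- summary(fit)$coefficients
    res$slope <- unname(sm["yr", "Estimate"])
    res$p_value <- unname(sm["yr", "Pr(>|t|)"])
    if (is.nan(res$p_value)) res$p_value <- 1  # perfect fit edge case
  } else {
    kt <- suppressWarnings(stats::cor.test(yr, v, method = "kendall"))
    res$p_value <- unname(kt$p.value)
    # Theil-Sen slope
    cmb <- utils::combn(length(v), 2)
    sl <- (v[cmb[2, ]] - v[cmb[1, ]]) / (yr[cmb[2, ]] - yr[cmb[1, ]])
    res$slope <- stats::median(sl[is.finite(sl)])
  }
  if (!is.na(res$p_value) && res$p_value < alpha) {
    if (res$slope > 0) res$trend_class <- "increasing"
    if (res$slope < 0) res$trend_class <- "decreasing"
  }
  class(res) <- "trend_result"
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Trend %d-%d (n=%d): mean %.4f, slope %s/yr, p %s -> %s%s\n",
    x$window[1], x$window[2], x$n, x$mean_value,
    ifelse(is.na(x$slope), "NA", sprintf("%.5f", x$slope)),
    ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3)),
    x$trend_class,
    if (x$insufficient_data) " (insufficient data)" else ""))
  invisible(x)
}

#' Windowed trends for every national series in an index table
#'
#' Applies [decadal_trend()] to one metric of an [annual_index_table()]
#' output, per country x taxon (country scope only).
#'
#' @param index_table An `IndexTable` data frame.
#' @param metric Column to analyse, e.g. `"stewards_ssii"` (default) or
#'   `"national_ssei"`.
#' @inheritParams decadal_trend
#' @return A data frame `(country, taxon, n, mean_value, slope, p_value,
#'   trend_class, insufficient_data)`.
#' @export
trend_table <- function(index_table, metric = "stewards_ssii",
                        window = c(2010, 2019), alpha = 0.01,
                        method = "ols") {
  it <- index_table[index_table$scope == "country", , drop = FALSE]
  keys <- unique(it[, c("country", "taxon")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- it[it$country == keys$country[i] & it$taxon == keys$taxon[i], ]
    tr <- decadal_trend(sub$year, sub[[metric]], window = window,
                        alpha = alpha, method = method)
    data.frame(country = keys$country[i], taxon = keys$taxon[i],
               n = tr$n, mean_value = tr$mean_value, slope = tr$slope,
               p_value = tr$p_value, trend_class = tr$trend_class,
               insufficient_data = tr$insufficient_data,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a nation into a coverage-status/trend typology quadrant
#'
#' The four national types cross decadal-mean coverage relative to the
#' global mean with the trend class: (1) below the global mean with no or
#' decreasing trend; (2) below with an increasing trend; (3) above with no
#' or decreasing trend; (4) above with an increasing trend. "Above" is a
#' strict inequality: a mean exactly equal to the global mean falls on the
#' "less than" side.
#'
#' @param mean_value National decadal mean of the index.
#' @param global_mean Unweighted mean of the national decadal means.
#' @param trend_class `"increasing"`, `"decreasing"`, or `"none"`
#'   (non-increasing classes are pooled).
#' @return Integer quadrant 1-4 (vectorized); `NA` for a missing mean.
#' @export
classify_typology <- function(mean_value, global_mean, trend_class) {
  stopifnot(all(trend_class %in% c("increasing", "decreasing", "none"),
                na.rm = TRUE))
  above <- mean_value > global_mean
  inc <- trend_class == "increasing"
  q <- ifelse(above, ifelse(inc, 4L, 3L), ifelse(inc, 2L, 1L))
  q[is.na(mean_value) | is.na(global_mean) | is.na(trend_class)] <- NA_integer_
  q
}

#' National typology table from trend results
#'
#' Computes the global mean (unweighted mean of national decadal means) for
#' a taxon and assigns every nation with sufficient data to a typology
#' quadrant via [classify_typology()].
#'
#' @param trends Output of [trend_table()], optionally filtered to one
#'   taxon.
#' @param taxon Taxon to classify (default: each taxon separately).
#' @return A data frame `(country, taxon, quadrant, mean_value,
#'   global_mean, trend_class)`; attribute `quadrant_pct` holds per-taxon
#'   percentage tables summing to 100.
#' @export
typology_table <- function(trends, taxon = NULL) {
  tr <- trends[!trends$insufficient_data & !is.na(trends$mean_value), ,
               drop = FALSE]
  tr <- tr[tr$country != "UNASSIGNED", , drop = FALSE]
  if (!is.null(taxon)) tr <- tr[tr$taxon %in% taxon, , drop = FALSE]
  if (nrow(tr) == 0) {
    out <- data.frame(country = character(), taxon = character(),
                      quadrant = integer(), mean_value = numeric(),
                      global_mean = numeric(), trend_class = character(),
                      stringsAsFactors = FALSE)
    attr(out, "quadrant_pct") <- list()
    return(out)
  }
  pieces <- lapply(split(tr, tr$taxon), function(sub) {
    gm <- mean(sub$mean_value)
    data.frame(country = sub$country, taxon = sub$taxon,
               quadrant = classify_typology(sub$mean_value, gm,
                                            sub$trend_class),
               mean_value = sub$mean_value, global_mean = gm,
               trend_class = sub$trend_class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  pct <- lapply(split(out, out$taxon), function(sub) {
    100 * table(factor(sub$quadrant, levels = 1:4)) / nrow(sub)
  })
  attr(out, "quadrant_pct") <- pct
  out
}

#' Stewardship-preference diagnostic
#'
#' Percent difference between Steward's and National SSII, relative to
#' National SSII: `100 * (stewards - national) / national`. Positive values
#' indicate that a nation preferentially covers the species for which it
#' holds high stewardship.
#'
#' @param national_ssii,stewards_ssii National and Steward's SSII values
#'   (vectorized).
#' @return Percent difference; `NA` where National SSII is 0 or missing.
#' @export
stewardship_preference <- function(national_ssii, stewards_ssii) {
  out <- 100 * (stewards_ssii - national_ssii) / national_ssii
  out[is.na(national_ssii) | national_ssii == 0] <- NA_real_
  out
}
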