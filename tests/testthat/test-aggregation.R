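# National/global aggregation, windowed trends, typology, and the
# stewardship-preference diagnostic.

test_that("National SSII is the unweighted mean over expected species", {
  expect_equal(national_ssii(c(5 / 6, 2 / 3)), 0.75)
  expect_equal(national_ssii(0.42), 0.42)
  expect_equal(national_ssii(rep(0, 5)), 0)
  expect_true(is.na(national_ssii(numeric(0))))
})

test_that("Steward's national SSII is the stewardship-weighted mean", {
  got <- stewards_national_ssii(c(5 / 6, 2 / 3), c(1, 0.3))
  expect_equal(got, (5 / 6 + 0.3 * 2 / 3) / 1.3)
  expect_equal(round(got, 1), 0.8)
  # equal weights reduce exactly to the unweighted mean
  cov <- c(0.1, 0.5, 0.9)
  expect_equal(stewards_national_ssii(cov, rep(0.2, 3)), mean(cov))
  # random triples vs explicit sum(w c)/sum(w)
  set.seed(3)
  for (rep in 1:10) {
    cov <- runif(3); w <- runif(3)
    expect_equal(stewards_national_ssii(cov, w), sum(w * cov) / sum(w))
  }
  expect_true(is.na(stewards_national_ssii(c(0.5, 0.5), c(0, 0))))
  expect_error(stewards_national_ssii(0.5, -1), "negative")
})

test_that("National SSEI averages available values only", {
  expect_equal(national_ssei(c(1, 0.5)), 0.75)
  expect_true(is.na(national_ssei(c(NA_real_, NA_real_))))
  vals <- c(0.2, NA, 0.8, NA, 0.5)
  expect_equal(national_ssei(vals), mean(vals[!is.na(vals)]))
  # weighted variant over the non-missing values
  expect_equal(national_ssei(c(1, NA, 0), c(3, 5, 1)), 3 / 4)
})

test_that("percentage of expected species recorded", {
  expect_equal(pct_species_recorded(letters[1:4], letters[1:3]), 75)
  expect_equal(pct_species_recorded(letters[1:4], character(0)), 0)
  expect_equal(pct_species_recorded(letters[1:4], letters[1:4]), 100)
  # recorded species outside the expected set are not credited
  expect_equal(pct_species_recorded(letters[1:4], c("a", "z")), 25)
  expect_true(is.na(pct_species_recorded(character(0), "a")))
  set.seed(9)
  for (rep in 1:10) {
    exp_set <- sample(letters, sample(3:10, 1))
    rec_set <- sample(letters, sample(1:10, 1))
    expect_equal(pct_species_recorded(exp_set, rec_set),
                 100 * length(intersect(rec_set, exp_set)) /
                   length(exp_set))
  }
})

test_that("annual index table has one row per scope-taxon-year and conserves records", {
  w <- make_world(n_countries = 2, n_species = c(ta = 3, tb = 3),
                  n_cols = 8, n_rows = 6, range_size = 30, lambda = 30,
                  years = 2017:2019, seed = 4)
  g <- grid_occurrences(w$occurrences, w$grid)
  si <- species_index_table(w$ranges, g, w$countries, years = 2017:2019)
  it <- annual_index_table(si, w$taxa)
  # with large ranges every taxon is expected everywhere:
  # 2 taxa x 3 years x (2 countries + global) = 18 rows
  expect_equal(nrow(it), 18L)
  expect_equal(anyDuplicated(it[, c("scope", "country", "taxon", "year")]),
               0L)
  # global record totals per year equal the gridded totals
  for (yr in 2017:2019) {
    expect_equal(sum(it$n_records[it$scope == "global" & it$year == yr]),
                 sum(g$counts$n_records[g$counts$year == yr]))
  }
  # national record counts (plus unassigned) sum to the global count
  expect_equal(sum(it$n_records[it$scope == "country"]),
               sum(it$n_records[it$scope == "global"]))
  expect_true(all(it$national_ssii >= 0 & it$national_ssii <= 1))
  expect_true(all(it$pct_species_recorded >= 0 &
                    it$pct_species_recorded <= 100))
})

test_that("annual table reproduces the worked-example national values", {
  fx <- fig1_fixture()
  g <- grid_occurrences(fx$occurrences, fx$grid)
  si <- species_index_table(fx$ranges, g, fx$countries, years = 2019)
  it <- annual_index_table(si, fx$taxa)
  aaa <- it[it$scope == "country" & it$country == "AAA", ]
  expect_equal(aaa$national_ssii, 0.75)
  expect_equal(round(aaa$stewards_ssii, 1), 0.8)
  expect_equal(aaa$pct_species_recorded, 100)
})

test_that("taxon-level global SSII equals the mean over species (property)", {
  for (seed in 1:5) {
    w <- small_world(seed)
    g <- grid_occurrences(w$occurrences, w$grid)
    si <- species_index_table(w$ranges, g, w$countries,
                              years = w$config$years)
    it <- annual_index_table(si, w$taxa)
    for (yr in w$config$years) {
      glob <- si[si$scope == "global" & si$year == yr, ]
      expect_equal(
        it$national_ssii[it$scope == "global" & it$year == yr],
        mean(glob$ssii))
    }
  }
})

test_that("species without a taxon are excluded and reported", {
  fx <- fig1_fixture()
  g <- grid_occurrences(fx$occurrences, fx$grid)
  si <- species_index_table(fx$ranges, g, fx$countries, years = 2019)
  it <- annual_index_table(si, data.frame(species_id = "sp1",
                                          taxon = "taxon1"))
  expect_equal(attr(it, "missing_taxon"), "sp2")
  expect_equal(it$n_species_expected[it$scope == "global"], 1L)
})

test_that("windowed OLS trend recovers exact lines and flags degenerate input", {
  yrs <- 2010:2019
  tr <- decadal_trend(yrs, 0.1 * (yrs - 2009))
  expect_equal(tr$slope, 0.1, tolerance = 1e-10)
  expect_lt(tr$p_value, 0.01)
  expect_equal(tr$trend_class, "increasing")
  expect_equal(tr$mean_value, mean(0.1 * (yrs - 2009)))

  const <- decadal_trend(yrs, rep(0.4, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$trend_class, "none")

  dec <- decadal_trend(yrs, 1 - 0.05 * (yrs - 2009) + rnorm(10, 0, 1e-6))
  expect_equal(dec$trend_class, "decreasing")

  few <- decadal_trend(c(2011, 2015), c(0.1, 0.9))
  expect_true(few$insufficient_data)
  expect_equal(few$trend_class, "none")
  expect_true(is.na(few$slope))

  # values outside the window are ignored
  win <- decadal_trend(c(1990, yrs), c(99, 0.1 * (yrs - 2009)),
                       window = c(2010, 2019))
  expect_equal(win$n, 10L)
  expect_equal(win$slope, 0.1, tolerance = 1e-10)
})

test_that("Mann-Kendall option classifies a clean monotone series", {
  yrs <- 2010:2019
  tr <- decadal_trend(yrs, 0.05 * (yrs - 2009), method = "mann-kendall")
  expect_equal(tr$trend_class, "increasing")
  expect_equal(tr$slope, 0.05, tolerance = 1e-10)
})

test_that("typology quadrants follow the four printed definitions", {
  expect_equal(classify_typology(0.2, 0.5, "none"), 1L)
  expect_equal(classify_typology(0.2, 0.5, "decreasing"), 1L)
  expect_equal(classify_typology(0.2, 0.5, "increasing"), 2L)
  expect_equal(classify_typology(0.7, 0.5, "none"), 3L)
  expect_equal(classify_typology(0.7, 0.5, "decreasing"), 3L)
  expect_equal(classify_typology(0.7, 0.5, "increasing"), 4L)
  # a mean exactly at the global mean is not "greater than"
  expect_equal(classify_typology(0.5, 0.5, "increasing"), 2L)
  expect_equal(classify_typology(0.5, 0.5, "none"), 1L)
  expect_true(is.na(classify_typology(NA, 0.5, "none")))
  expect_error(classify_typology(0.5, 0.5, "sideways"), "trend_class")
})

test_that("typology table partitions countries and percentages sum to 100", {
  trends <- data.frame(
    country = sprintf("C%02d", 1:8), taxon = "ta",
    n = 10, mean_value = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9),
    slope = 0.01, p_value = rep(c(0.5, 0.001), 4),
    trend_class = rep(c("none", "increasing"), 4),
    insufficient_data = FALSE, stringsAsFactors = FALSE)
  ty <- typology_table(trends)
  expect_equal(nrow(ty), 8L)
  expect_false(any(is.na(ty$quadrant)))
  pct <- attr(ty, "quadrant_pct")$ta
  expect_equal(sum(pct), 100)
  # global mean is the unweighted mean of national means
  expect_equal(unique(ty$global_mean), mean(trends$mean_value))
})

test_that("stewardship preference is the percent difference vs National SSII", {
  expect_equal(round(stewardship_preference(0.75, 0.7948718), 1), 6.0)
  expect_equal(stewardship_preference(0.4, 0.4), 0)
  expect_equal(stewardship_preference(0.5, 0.25), -50)
  expect_true(is.na(stewardship_preference(0, 0.1)))
})
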