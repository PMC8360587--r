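# Species-level SSII, stewardship, and SSEI.

test_that("coverage is the sampled fraction of the expected range", {
  expect_equal(species_coverage(1:6, 1:5), 5 / 6)
  expect_equal(species_coverage(1:3, 1:2), 2 / 3)
  expect_equal(species_coverage(1:4, integer(0)), 0)
  expect_equal(species_coverage(1:4, 1:4), 1)
  # out-of-range sampled cells are ignored, not credited
  expect_equal(species_coverage(1:4, c(1, 99)), 0.25)
  expect_error(species_coverage(integer(0), 1), "undefined")
})

test_that("stewardship weights are range-cell fractions summing to 1", {
  assign6 <- data.frame(cell_id = 0:5, country = "AAA")
  w <- stewardship_weights(0:5, assign6)
  expect_equal(w$weight, 1)  # country endemic
  expect_equal(w$country, "AAA")

  # 10-cell range, 3 cells in B
  assign10 <- data.frame(cell_id = 0:9,
                         country = c(rep("BBB", 3), rep("CCC", 7)))
  w2 <- stewardship_weights(0:9, assign10)
  expect_equal(w2$weight[w2$country == "BBB"], 0.3)
  expect_equal(sum(w2$weight), 1)

  # symmetric three-way split
  assign3 <- data.frame(cell_id = 0:5,
                        country = rep(c("AAA", "BBB", "CCC"), each = 2))
  w3 <- stewardship_weights(0:5, assign3)
  expect_equal(w3$weight, rep(1 / 3, 3))

  # unassigned remainder keeps the weights a partition of unity
  w4 <- stewardship_weights(0:9, assign6)
  expect_equal(w4$weight[w4$country == "UNASSIGNED"], 0.4)
  expect_equal(sum(w4$weight), 1)
})

test_that("Steward's species SSII is coverage times stewardship", {
  expect_equal(round(stewards_species_ssii(5 / 6, 1), 2), 0.83)
  expect_equal(round(stewards_species_ssii(2 / 3, 0.3), 2), 0.2)
  expect_equal(stewards_species_ssii(0.9, 0), 0)
})

test_that("global SSII matches brute-force set intersection", {
  set.seed(5)
  for (rep in 1:20) {
    expected <- sample(0:50, 12)
    counts <- data.frame(
      species_id = "sp", year = 2019,
      cell_id = sample(0:50, sample(1:20, 1)),
      n_records = 1L, stringsAsFactors = FALSE)
    got <- species_global_ssii(expected, counts, "sp", 2019)
    want <- length(intersect(unique(counts$cell_id), expected)) / 12
    expect_equal(got, want)
  }
})

test_that("SSEI is 1 for uniform counts at any sampling depth", {
  for (c in c(1, 10, 1000)) {
    expect_equal(species_ssei(rep(c, 3)), 1)
    expect_equal(species_ssei(rep(c, 25)), 1)
  }
})

test_that("SSEI matches an independent high-precision evaluation", {
  # frozen from an arbitrary-precision entropy computation of
  # H([1,1,1,1000]) / ln(4)
  expect_equal(species_ssei(c(1, 1, 1, 1000)), 0.01706476750843976,
               tolerance = 1e-14)
})

test_that("SSEI conventions for a single sampled cell", {
  expect_true(is.na(species_ssei(7)))
  expect_equal(species_ssei(7, single_cell = "zero"), 0)
  expect_equal(species_ssei(7, single_cell = "one"), 1)
  expect_error(species_ssei(c(1, 0)), "positive")
})

test_that("SSEI with the expected-range denominator penalizes unsampled cells", {
  # 3 uniformly sampled cells of a 6-cell range: H = ln 3, SSEI = ln3/ln6
  expect_equal(species_ssei(c(2, 2, 2), denominator = "expected",
                            n_expected = 6), log(3) / log(6))
  expect_error(species_ssei(c(1, 2), denominator = "expected"), "n_expected")
})

test_that("SSEI invariances and majorization (property)", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:15, 1)
    counts <- sample(1:40, n, replace = TRUE)
    s <- species_ssei(counts)
    expect_gte(s, 0); expect_lte(s, 1)
    # invariant under uniform scaling
    expect_equal(species_ssei(counts * 7), s, tolerance = 1e-12)
    # equals 1 iff exactly uniform
    expect_equal(s == 1, length(unique(counts)) == 1)
    # moving a record from the least- to the most-sampled cell strictly
    # decreases evenness (skip when that transfer empties the cell)
    lo <- which.min(counts); hi <- which.max(counts)
    if (counts[lo] > 1 && lo != hi) {
      shifted <- counts
      shifted[lo] <- shifted[lo] - 1L
      shifted[hi] <- shifted[hi] + 1L
      expect_lt(species_ssei(shifted), s)
    }
    expect_equal(s, brute_ssei(counts), tolerance = 1e-12)
  }
})

test_that("adding records changes SSII only through newly sampled cells", {
  counts <- data.frame(species_id = "sp", year = 2019,
                       cell_id = c(0L, 1L), n_records = c(2L, 1L),
                       stringsAsFactors = FALSE)
  base <- species_global_ssii(0:5, counts, "sp", 2019)
  # new record in an unsampled expected cell: strict increase
  more <- rbind(counts, data.frame(species_id = "sp", year = 2019,
                                   cell_id = 2L, n_records = 1L))
  expect_gt(species_global_ssii(0:5, more, "sp", 2019), base)
  # deeper sampling of an already-sampled cell: no change
  deeper <- counts
  deeper$n_records[1] <- 50L
  expect_equal(species_global_ssii(0:5, deeper, "sp", 2019), base)
})

test_that("species_year_indices reproduces the worked example", {
  fx <- fig1_fixture()
  g <- grid_occurrences(fx$occurrences, fx$grid)
  sp1_cells <- fx$ranges$cell_id[fx$ranges$species_id == "sp1"]
  sp2_cells <- fx$ranges$cell_id[fx$ranges$species_id == "sp2"]

  r1 <- species_year_indices(sp1_cells, g, "sp1", 2019,
                             assignment = fx$countries, country = "AAA")
  expect_equal(round(r1$ssii, 2), 0.83)
  expect_equal(round(r1$stewards_ssii, 2), 0.83)
  expect_equal(r1$weight, 1)

  r2 <- species_year_indices(sp2_cells, g, "sp2", 2019,
                             assignment = fx$countries, country = "AAA")
  expect_equal(round(r2$ssii, 2), 0.67)
  expect_equal(round(r2$stewards_ssii, 2), 0.2)
  expect_equal(r2$weight, 0.3)

  # a year with no records: coverage 0, SSEI missing
  r0 <- species_year_indices(sp1_cells, g, "sp1", 1999)
  expect_equal(r0$ssii, 0)
  expect_true(is.na(r0$ssei))
  expect_equal(r0$n_records, 0L)

  expect_error(
    species_year_indices(sp1_cells, g, "sp1", 2019,
                         assignment = fx$countries, country = "ZZZ"),
    "unknown country")
})

test_that("Steward's SSII sums over countries to the global SSII (property)", {
  for (seed in 1:12) {
    w <- small_world(seed)
    g <- grid_occurrences(w$occurrences, w$grid)
    si <- species_index_table(w$ranges, g, w$countries,
                              years = w$config$years)
    glob <- si[si$scope == "global", ]
    for (i in seq_len(nrow(glob))) {
      nat <- si[si$scope == "country" &
                  si$species_id == glob$species_id[i] &
                  si$year == glob$year[i], ]
      expect_equal(sum(nat$stewards_ssii), glob$ssii[i],
                   tolerance = 1e-12)
      expect_equal(sum(nat$weight), 1, tolerance = 1e-12)
    }
  }
})

test_that("out-of-range records are excluded and reported", {
  g <- toy_grid()
  cells <- c(0, 1, 12)  # record in cell 12 is outside the 0:5 range
  ctr <- cell_centers(g, cells)
  ll <- unproject_xy(ctr[, "x"], ctr[, "y"], g$projection)
  occ <- data.frame(species = "sp", decimalLongitude = ll[, "lon"],
                    decimalLatitude = ll[, "lat"], year = 2019)
  gr <- grid_occurrences(occ, g)
  ranges <- data.frame(species_id = "sp", cell_id = 0:5)
  si <- species_index_table(ranges, gr, NULL, years = 2019)
  expect_equal(si$ssii[si$scope == "global"], 2 / 6)
  oor <- attr(si, "out_of_range")
  expect_equal(oor$n_records, 1L)
})
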