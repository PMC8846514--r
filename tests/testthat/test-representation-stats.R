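test_that("country tabulation partitions records with an Unknown row", {
  recs <- make_located(c(rep("United States", 3), rep(NA, 2),
                         rep("China", 5)))
  tab <- tabulate_samples(recs, "country")
  expect_equal(tab$samples[tab$unit == "China"], 5L)
  expect_equal(tab$samples[tab$unit == "United States"], 3L)
  expect_equal(tab$samples[tab$unit == "Unknown"], 2L)
  expect_equal(sum(tab$samples), nrow(recs))
  # brute-force oracle
  oracle <- oracle_tabulate_country(recs)
  expect_equal(sort(tab$samples), sort(unname(oracle)))
})

test_that("body-site table counts all samples but only resolved countries", {
  recs <- make_located(c("United States", "Chile", NA), body_site = "Gut")
  tab <- tabulate_samples(recs, "body_site")
  expect_equal(tab$samples, 3L)
  expect_equal(tab$countries, 2L)
})

test_that("empty input tabulates to an empty table", {
  empty <- make_located(character())
  expect_equal(nrow(tabulate_samples(empty, "country")), 0)
  expect_equal(nrow(tabulate_samples(empty, "body_site")), 0)
  expect_equal(nrow(time_series(empty)), 0)
})

test_that("shares reproduce published country-level rounding", {
  counts <- tibble::tibble(
    unit = c("US", "China", "Unknown"),
    samples = c(178960L, 36162L, 62118L))
  tab <- shares(counts, total_all = 444829, total_known = 382711)
  expect_equal(round_half_up(100 * tab$share_all, 1), c(40.2, 8.1, 14.0))
  one <- shares(tibble::tibble(unit = "A", samples = 10L))
  expect_equal(one$share_all, 1)
  expect_error(shares(counts, total_all = 0),
               class = "geosample_input_error")
})

test_that("representation proportion is share ratio with guarded domain", {
  expect_equal(representation_proportion(0.25, 0.25), 1)
  expect_equal(representation_proportion(0.5, 0.1), 5)
  expect_error(representation_proportion(0, 0.1),
               class = "geosample_input_error")
  expect_error(representation_proportion(0.1, 0),
               class = "geosample_input_error")
})

test_that("raw index uses the ratio or its negative reciprocal", {
  expect_equal(raw_index(2, 1), 2)
  expect_equal(raw_index(1, 2), -2)
  expect_equal(raw_index(1, 1), 1)  # proportionality tie-break: positive branch
  expect_true(is.na(raw_index(0, 1)))
  expect_error(raw_index(-1, 1), class = "geosample_input_error")
  # underrepresentation magnitude from published regional counts
  sample_share <- 100 * (6685 / 382570)
  pop_share <- 100 * (2014709 / 7794799)
  expect_equal(raw_index(sample_share, pop_share),
               -(pop_share / sample_share))
  expect_equal(round_half_up(raw_index(sample_share, pop_share), 1), -14.8)
})

test_that("raw index is antisymmetric under swapping the shares", {
  set.seed(71)
  a <- runif(200, 0.01, 10)
  b <- runif(200, 0.01, 10)
  keep <- a != b
  expect_equal(raw_index(a, b)[keep], -raw_index(b, a)[keep])
})

test_that("index scaling anchors the maxima, excludes low counts, keeps order", {
  rows <- tibble::tibble(samples = c(500, 400, 300, 200, 50, 10),
                         raw_index = c(2, 4, -3, -6, 9, NA))
  scaled <- scale_indices(rows, min_samples = 50)
  expect_equal(scaled$scaled_index[1:4], c(50, 100, -50, -100))
  expect_equal(scaled$index_note[5], "excluded_low_n")  # 50 is "50 or fewer"
  expect_equal(scaled$index_note[6], "no_samples")
  one <- scale_indices(tibble::tibble(samples = 100, raw_index = 7), 50)
  expect_equal(one$scaled_index, 100)
  # sign and within-sign ordering preserved on random draws
  set.seed(5)
  r <- tibble::tibble(samples = 1000, raw_index = runif(100, -20, 20))
  s <- scale_indices(r, 50)
  expect_equal(sign(s$scaled_index), sign(s$raw_index))
  expect_equal(order(s$scaled_index), order(s$raw_index))
})

test_that("display transform is sign-preserving, zero-fixed, and monotone", {
  expect_equal(display_transform(0), 0)
  expect_equal(display_transform(100), log10(101))
  expect_equal(display_transform(-100), -log10(101))
  grid <- seq(-100, 100, length.out = 1000)
  expect_true(all(diff(display_transform(grid)) > 0))
})

test_that("time series accumulates annual counts per region", {
  recs <- make_located(rep("United States", 4),
                       region = "Europe and Northern America",
                       release_date = as.Date(c("2019-03-01", "2019-07-01",
                                                "2020-01-01", "2020-06-01")))
  ts <- time_series(recs)
  expect_equal(ts$samples_released, c(2L, 2L))
  expect_equal(ts$cumulative_samples, c(2L, 4L))
  expect_equal(ts$annual_share, c(1, 1))
  # single-year cohort: cumulative equals annual
  one <- time_series(make_located("Chile",
                                  region = "Latin America and the Caribbean",
                                  release_date = as.Date("2020-02-02")))
  expect_equal(one$cumulative_samples, one$samples_released)
})

test_that("time series matches generator truth and conserves counts", {
  coh <- generate_cohort(cohort_config(1500, seed = 44))
  geo <- attribute_geography(coh$records, ref_world, ref_gazetteer)
  ts <- time_series(geo$records)
  annual <- tapply(ts$samples_released, ts$year, sum)
  truth <- coh$truth$by_year
  expect_equal(annual[names(truth)], unclass(truth)[names(truth)],
               ignore_attr = TRUE)
  expect_true(all(tapply(ts$cumulative_samples, ts$region,
                         function(x) all(diff(x) >= 0))))
  share_sums <- tapply(ts$annual_share, ts$year, sum)
  share_sums <- share_sums[!is.na(share_sums)]  # years with zero releases
  expect_true(all(abs(share_sums - 1) < 1e-9))
})

test_that("representation table reproduces printed regional share rounding", {
  snapshot <- readr::read_csv(geosample_extdata("region_snapshot_2021.csv"),
                              show_col_types = FALSE)
  regions <- snapshot[snapshot$group %in% c("region", "region_unknown"),
                      c("unit", "samples", "population_thousands")]
  tab <- representation_table(regions)
  eur <- tab[tab$unit == "Europe and Northern America", ]
  expect_equal(round_half_up(100 * eur$share_known, 1), 71.2)
  expect_equal(round_half_up(100 * eur$share_all, 1), 61.3)
  expect_equal(round_half_up(100 * eur$pop_share, 1), 14.3)
  unk <- tab[tab$unit == "Unknown", ]
  expect_equal(round_half_up(100 * unk$share_all, 1), 14.0)
  expect_true(is.na(unk$repr_proportion))
})
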