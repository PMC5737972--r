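test_that("default band geometry matches the 120/145/3 cell accounting", {
  sp <- lexis_spec()
  bands <- default_trend_bands(sp)
  expect_length(bands, 7L)
  n <- vapply(bands, function(b) nrow(b$cells), integer(1))
  # three horizontal 5-year age bands over 8 years: 40 cells each
  expect_identical(unname(n[c("age_50_54", "age_55_59", "age_60_64")]),
                   c(40L, 40L, 40L))
  expect_identical(sum(n[1:3]), 120L)
  # four diagonal bands: 145 cells in total
  expect_identical(sum(n[4:7]), 145L)
  expect_identical(unname(n["cohort_45_49"]), 25L)
  # the cohorts reaching age 50 in 2006 and 2007 traverse exactly 3 cells,
  # omitted from every default band
  cells <- lexis_cells(sp)
  coh <- cells$age - (cells$year - 2000)
  stray <- cells[coh %in% c(43, 44) & cells$year <= 2007, ]
  expect_identical(nrow(stray), 3L)
  all_band_cells <- do.call(rbind, lapply(bands[4:7], `[[`, "cells"))
  expect_false(any(paste(stray$age, stray$year) %in%
                     paste(all_band_cells$age, all_band_cells$year)))
})

make_trend_grid <- function(sp, counts1, counts0 = counts1, wy = 1000) {
  df <- expand.grid(age = sp$ages, year = sp$years, region = sp$regions,
                    KEEP.OUT.ATTRS = FALSE)
  df$stage24_cases <- ifelse(df$region == 1,
                             counts1[match(df$year, sp$years)],
                             counts0[match(df$year, sp$years)])
  wyt <- df[c("age", "year", "region")]
  wyt$women_years <- wy
  lexis_grid(sp, stage24_cases = df[c("age", "year", "region",
                                      "stage24_cases")],
             women_years = wyt)
}

test_that("Poisson band slopes recover exact log-linear data", {
  sp <- lexis_spec(ages = 50:54, years = 2000:2002)
  band <- age_band(sp, c(50, 54), years = sp$years)
  # perfectly log-linear counts with ratio 2 per year: slope +100%
  g <- make_trend_grid(sp, c(100L, 200L, 400L))
  expect_equal(band_annual_change(g, band, 1), 100, tolerance = 1e-8)
  # constant rates: 0% per year
  g0 <- make_trend_grid(sp, c(150L, 150L, 150L))
  expect_equal(band_annual_change(g0, band, 1), 0, tolerance = 1e-8)
  # two years, equal person-time, 100 then 90: exp(log(90/100)) - 1 = -10%
  sp2 <- lexis_spec(ages = 50:54, years = 2000:2001)
  g2 <- make_trend_grid(sp2, c(100L, 90L))
  expect_equal(band_annual_change(g2, age_band(sp2, c(50, 54),
                                               years = sp2$years), 1),
               -10, tolerance = 1e-8)
})

test_that("band slopes are invariant to rescaling person-time", {
  sp <- lexis_spec(ages = 50:54, years = 2000:2005)
  band <- age_band(sp, c(50, 54), years = sp$years)
  set.seed(41)
  counts <- rpois(6, 80) + 1L
  g1 <- make_trend_grid(sp, counts, wy = 500)
  g2 <- make_trend_grid(sp, counts, wy = 500 * 7.3)
  expect_equal(band_annual_change(g1, band, 1),
               band_annual_change(g2, band, 1), tolerance = 1e-8)
})

test_that("undefined trends raise informative errors", {
  sp <- lexis_spec(ages = 50:54, years = 2000:2002)
  band <- age_band(sp, c(50, 54), years = sp$years)
  g <- make_trend_grid(sp, c(0L, 0L, 0L))
  expect_error(band_annual_change(g, band, 1), "all counts are zero")
  sp1 <- lexis_spec(ages = 50:54, years = 2000)
  expect_error(
    band_annual_change(make_trend_grid(sp1, 10L),
                       age_band(sp1, c(50, 54), years = sp1$years), 1),
    "2 distinct years")
})

test_that("band_trends tabulates every band for both regions", {
  sp <- lexis_spec()
  part <- partition_cells(sp)
  wy <- study_women_years(sp, part)
  g <- simulate_stage24_grid(sp, part, wy, 1.9e-3, seed = 42)
  tab <- band_trends(g)
  expect_identical(nrow(tab), 14L)  # 7 bands x 2 regions
  expect_true(all(is.finite(tab$pct_per_year)))
})

test_that("yearly matched ratios reduce to crude ratios on one age", {
  sp <- lexis_spec(ages = 50, years = 2000:2013)
  part <- partition_cells(sp)   # a single age 50: always eligible
  set.seed(43)
  df <- expand.grid(age = 50L, year = sp$years, region = sp$regions,
                    KEEP.OUT.ATTRS = FALSE)
  df$stage24_cases <- rpois(nrow(df), 30)
  wy <- df[c("age", "year", "region")]
  wy$women_years <- ifelse(wy$region == 1, 1200, 1000)
  g <- lexis_grid(sp, stage24_cases = df, women_years = wy)
  ym <- yearly_mh_ratios(g, part)
  for (i in seq_len(nrow(ym))) {
    d <- df[df$year == ym$year[i], ]
    crude <- (d$stage24_cases[d$region == 1] / 1200) /
      (d$stage24_cases[d$region == 2] / 1000)
    expect_equal(ym$estimate[i], crude)
  }
})

test_that("yearly ratios mark event-free years as undefined, not errors", {
  sp <- lexis_spec(ages = 50:52, years = 2000:2002)
  part <- partition_cells(sp)
  df <- expand.grid(age = sp$ages, year = sp$years, region = sp$regions,
                    KEEP.OUT.ATTRS = FALSE)
  df$stage24_cases <- ifelse(df$year == 2001, 0L, 4L)
  wy <- df[c("age", "year", "region")]
  wy$women_years <- 100
  g <- lexis_grid(sp, stage24_cases = df, women_years = wy)
  ym <- yearly_mh_ratios(g, part)
  expect_true(is.na(ym$estimate[ym$year == 2001]))
  expect_false(anyNA(ym$estimate[ym$year != 2001]))
})

test_that("yearly ratios hover near 1 under an exchangeable null", {
  sp <- lexis_spec()
  part <- partition_cells(sp)
  wy <- study_women_years(sp, part)
  g <- simulate_stage24_grid(sp, part, wy, 1.9e-3, background_ratio = 1,
                             coef = 0, seed = 44)
  ym <- yearly_mh_ratios(g, part)
  expect_true(all(abs(log(ym$estimate)) < 4 * sqrt(1 / ym$D1 + 1 / ym$D0)))
  expect_lt(abs(mean(log(ym$estimate))), 0.03)
})
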