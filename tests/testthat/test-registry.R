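test_that("well-formed files round-trip through read/write", {
  df <- rbind(make_records(1, 2003, 60, "stage2_4", 2010, "breast_cancer"),
              make_records(2, 2005, 55, "stage1"),
              make_records(1, 2001, 70, "unknown", 2002, "other"))
  for (ext in c("csv", "tsv")) {
    path <- write_tmp_registry(df, ext)
    rec <- read_registry(path)
    expect_identical(nrow(rec), 3L)
    expect_identical(nrow(attr(rec, "rejected")), 0L)
    out <- tempfile(fileext = paste0(".", ext))
    write_registry(rec, out)
    expect_identical(as.data.frame(read_registry(out)),
                     as.data.frame(rec))
  }
})

test_that("invalid rows are rejected with line-level diagnostics", {
  df <- rbind(
    make_records(),                                           # fine
    make_records(death_year = 2001, death_cause = "breast_cancer"),
    make_records(stage_class = "stageX"),
    make_records(death_cause = "breast_cancer"),              # cause, no year
    make_records(age_dx = -3))
  path <- write_tmp_registry(df)
  expect_message(rec <- read_registry(path), "rejected 4 of 5")
  rej <- attr(rec, "rejected")
  expect_identical(nrow(rec), 1L)
  expect_identical(rej$line, c(3L, 4L, 5L, 6L))  # header is line 1
  expect_true(any(grepl("death_year before year_dx", rej$reason)))
  expect_true(any(grepl("invalid stage_class", rej$reason)))
  expect_true(any(grepl("without death_year", rej$reason)))
})

test_that("missing mandatory columns are a hard error, empty files are not", {
  df <- make_records()
  df$stage_class <- NULL
  expect_error(read_registry(write_tmp_registry(df)),
               "missing mandatory column")
  empty <- make_records()[0, ]
  rec <- read_registry(write_tmp_registry(empty))
  expect_identical(nrow(rec), 0L)
})

test_that("column mapping config renames file columns", {
  df <- make_records(1, 2003, 60, "stage2_4", 2010, "breast_cancer")
  names(df) <- c("area", "dx_yr", "dx_age", "stage", "death_yr", "cause")
  path <- write_tmp_registry(df)
  map <- list(region = "area", year_dx = "dx_yr", age_dx = "dx_age",
              stage_class = "stage", death_year = "death_yr",
              death_cause = "cause")
  rec <- read_registry(path, map)
  expect_identical(rec$age_dx, 60L)
  yml <- tempfile(fileext = ".yaml")
  writeLines(vapply(names(map), function(k)
    paste0(k, ": ", map[[k]]), character(1)), yml)
  expect_identical(as.data.frame(read_registry(path, yml)),
                   as.data.frame(rec))
})

test_that("incidence-based mortality tabulation applies every filter", {
  sp <- lexis_spec()
  df <- rbind(
    # pre-programme diagnosis: the death cannot count
    make_records(1, 1998, 55, "stage2_4", 2005, "breast_cancer"),
    # all filters pass: cell (70, 2010)
    make_records(1, 2003, 63, "stage2_4", 2010, "breast_cancer"),
    # non-breast cause
    make_records(1, 2003, 60, "stage2_4", 2010, "other"),
    # death beyond follow-up
    make_records(2, 2003, 60, "stage2_4", 2014, "breast_cancer"),
    # death at age 85: outside the 50-84 death window
    make_records(2, 2000, 80, "stage2_4", 2005, "breast_cancer"),
    # diagnosed before 50
    make_records(2, 2002, 49, "stage2_4", 2006, "breast_cancer"))
  g <- tabulate_mortality(as_registry_records(df), sp)
  expect_identical(sum(g$deaths), 1L)
  expect_identical(g$deaths[g$age == 70 & g$year == 2010 & g$region == 1],
                   1L)
  ex <- attr(g, "exclusions")
  expect_identical(unname(ex["pre_window_diagnosis"]), 1L)
  expect_identical(unname(ex["death_outside_followup"]), 1L)
  expect_identical(unname(ex["death_age_outside_window"]), 1L)
  expect_identical(unname(ex["young_diagnosis"]), 1L)
})

test_that("stage 2-4 tabulation counts in-grid stage 2-4 diagnoses only", {
  sp <- lexis_spec()
  df <- rbind(
    make_records(1, 2005, 60, "stage2_4"),
    make_records(1, 2005, 60, "stage1"),
    make_records(2, 2005, 60, "stage2_4"),
    make_records(2, 2005, 45, "stage2_4"),   # below grid ages
    make_records(1, 1999, 60, "stage2_4"),   # before grid years
    make_records(1, 2006, 61, "unknown"),
    make_records(1, 2007, 62, "stage2_4"),
    make_records(2, 2008, 70, "stage2_4"),
    make_records(2, 2009, 88, "stage1"),
    make_records(1, 2010, 90, "stage2_4"))   # above grid ages
  g <- tabulate_stage24(as_registry_records(df), sp)
  expect_identical(sum(g$stage24_cases), 4L)  # hand count of the fixture
  expect_identical(g$stage24_cases[g$age == 60 & g$year == 2005 &
                                     g$region == 1], 1L)
  ex <- attr(g, "exclusions")
  expect_identical(unname(ex["unknown_stage"]), 1L)
  expect_identical(unname(ex["outside_grid"]), 3L)
})

test_that("tabulation is order-invariant and bounded by the record count", {
  sp <- lexis_spec()
  set.seed(21)
  df <- make_records(region = sample(1:2, 60, TRUE),
                     year_dx = sample(2000:2013, 60, TRUE),
                     age_dx = sample(48:86, 60, TRUE),
                     stage_class = sample(c("stage1", "stage2_4", "unknown"),
                                          60, TRUE))
  rec <- as_registry_records(df)
  shuffled <- as_registry_records(df[sample(nrow(df)), ])
  g1 <- tabulate_stage24(rec, sp)
  g2 <- tabulate_stage24(shuffled, sp)
  expect_identical(g1$stage24_cases, g2$stage24_cases)
  expect_lte(sum(g1$stage24_cases), nrow(rec))
  m1 <- tabulate_mortality(rec, sp)
  m2 <- tabulate_mortality(shuffled, sp)
  expect_identical(m1$deaths, m2$deaths)
  expect_lte(sum(m1$deaths), nrow(rec))
})

test_that("grids serialize losslessly and enforce their invariants", {
  sp <- lexis_spec(ages = 50:52, years = 2000:2001)
  wy <- expand.grid(age = sp$ages, year = sp$years, region = sp$regions,
                    KEEP.OUT.ATTRS = FALSE)
  wy$women_years <- 100
  df <- rbind(make_records(1, 2000, 51, "stage2_4", 2001, "breast_cancer"),
              make_records(2, 2000, 50, "stage2_4"))
  g <- build_lexis_grid(as_registry_records(df), wy, sp,
                        death_age_range = c(50, 84))
  path <- tempfile(fileext = ".csv")
  write_lexis_grid(g, path)
  g2 <- read_lexis_grid(path)
  attr(g, "exclusions") <- NULL
  expect_equal(as.data.frame(g2), as.data.frame(g))
  # zero person-time under an event is a structural violation
  bad <- g
  bad$women_years[bad$stage24_cases > 0][1] <- 0
  expect_error(validate_lexis_grid(bad), "zero person-time")
  bad2 <- g
  bad2$deaths[1] <- -1L
  expect_error(validate_lexis_grid(bad2), "non-negative integer")
})
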