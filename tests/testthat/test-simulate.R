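small_cfg <- function(...) sim_config(cohort_size = 200L, ...)

test_that("identical config and seed give byte-identical output", {
  s1 <- simulate_registry(small_cfg(), 17)
  s2 <- simulate_registry(small_cfg(), 17)
  expect_identical(as.data.frame(s1$records), as.data.frame(s2$records))
  expect_identical(s1$women_years, s2$women_years)
  s3 <- simulate_registry(small_cfg(), 18)
  expect_false(identical(as.data.frame(s1$records),
                         as.data.frame(s3$records)))
})

test_that("config invariants are enforced before any simulation", {
  expect_error(sim_config(participation = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(stage_shift = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(baseline_hazard = function(age) age), "\\[0, 1\\]")
  expect_error(sim_config(fatality = c(stage1 = 0.01)), "stage2_4")
  expect_error(sim_config(schedules = list(invitation_schedule(2000))),
               "two invitation_schedule")
  expect_error(sim_config(schedules = list(invitation_schedule(1998),
                                           invitation_schedule(2008))),
               "before the study window")
})

test_that("zero hazards give an all-zero expected event surface", {
  cfg <- small_cfg(baseline_hazard = function(age) rep(0, length(age)))
  ex <- expected_cell_rates(cfg)
  expect_true(all(ex$cases_stage1 == 0))
  expect_true(all(ex$cases_stage24 == 0))
  expect_true(all(ex$deaths == 0))
  expect_true(all(ex$women_years > 0))
  sim <- simulate_registry(cfg, 3)
  expect_identical(nrow(sim$records), 0L)
})

test_that("single cohort at small constant hazard: cases about N*h per year", {
  h <- 5e-4
  cfg <- sim_config(cohort_size = 10000L, cohort_ages = 50L,
                    baseline_hazard = function(age) rep(h, length(age)),
                    participation = 0,
                    fatality = c(stage1 = 0, stage2_4 = 0))
  ex <- expected_cell_rates(cfg)
  cases <- ex$cases_stage1 + ex$cases_stage24
  expect_identical(nrow(ex), 2L * 14L)  # one cohort diagonal per region
  expect_true(all(abs(cases / (10000 * h) - 1) < 0.01))
})

test_that("participation mixes the full-effect and null expectations exactly", {
  base <- list(cohort_size = 500L, cohort_ages = 48:55)
  e1 <- expected_cell_rates(do.call(sim_config,
                                    c(base, participation = 1)))
  e0 <- expected_cell_rates(do.call(sim_config,
                                    c(base, participation = 0)))
  e7 <- expected_cell_rates(do.call(sim_config,
                                    c(base, participation = 0.7)))
  for (col in c("cases_stage24", "deaths", "women_years")) {
    expect_equal(e7[[col]], 0.7 * e1[[col]] + 0.3 * e0[[col]],
                 tolerance = 1e-10)
  }
  # invited-cohort mortality ratio is the participation-weighted mixture
  d1 <- sum(e1$deaths[e1$region == 1]); d0 <- sum(e0$deaths[e0$region == 1])
  d7 <- sum(e7$deaths[e7$region == 1])
  r <- d1 / d0
  expect_equal(d7 / d0, 0.7 * r + 0.3, tolerance = 1e-10)
})

test_that("simulated cell means track the analytic expectations", {
  cfg <- sim_config(cohort_size = 4000L, cohort_ages = 48:60)  # ~1e5 women
  sim <- simulate_registry(cfg, 70)
  ex <- expected_cell_rates(cfg)
  g <- build_lexis_grid(sim$records, sim$women_years, cfg$spec)
  for (r in cfg$spec$regions) {
    eo <- sum(g$stage24_cases[g$region == r])
    ee <- sum(ex$cases_stage24[ex$region == r])
    expect_lt(abs(eo - ee), 3 * sqrt(ee))
    do <- sum(g$deaths[g$region == r])
    de <- sum(ex$deaths[ex$region == r])
    expect_lt(abs(do - de), 3 * sqrt(de))
    wo <- sum(g$women_years[g$region == r])
    we <- sum(ex$women_years[ex$region == r])
    expect_lt(abs(wo / we - 1), 0.005)  # person-time is almost deterministic
  }
  # stage 1 cases from the raw records, on-grid only
  rec <- as.data.frame(sim$records)
  on_grid <- rec$age_dx %in% cfg$spec$ages & rec$year_dx %in% cfg$spec$years
  s1o <- sum(rec$stage_class == "stage1" & on_grid)
  s1e <- sum(ex$cases_stage1)
  expect_lt(abs(s1o - s1e), 3 * sqrt(s1e))
})

test_that("stage shift yields a prevalence-round excess then a deficit", {
  cfg <- sim_config(cohort_size = 1000L)
  ex <- expected_cell_rates(cfg)
  part <- partition_cells(cfg$spec)
  lab <- part$label[match(paste(ex$age, ex$year),
                          paste(part$age, part$year))]
  el <- ex[lab == "eligible", ]
  ratio <- sapply(cfg$spec$years, function(y) {
    a <- el[el$year == y & el$region == 1, ]
    b <- el[el$year == y & el$region == 2, ]
    (sum(a$cases_stage24) / sum(a$women_years)) /
      (sum(b$cases_stage24) / sum(b$women_years))
  })
  names(ratio) <- cfg$spec$years
  # first screening round harvests stage 2-4 cases: transient excess
  expect_gt(ratio[["2000"]], 1)
  # thereafter the earlier-screened region runs a deficit until the other
  # region's programme starts
  expect_true(all(ratio[as.character(2001:2007)] < 1))
  # the two regions' rates converge once both programmes run
  expect_lt(abs(ratio[["2013"]] - 1), abs(ratio[["2007"]] - 1))
})

test_that("mortality benefit appears only after the first invitation round", {
  base <- list(cohort_size = 1000L,
               schedules = list(invitation_schedule(2004),
                                invitation_schedule(2014)))
  off <- list(cohort_size = 1000L,
              schedules = list(invitation_schedule(2014),
                               invitation_schedule(2014)))
  ea <- expected_cell_rates(do.call(sim_config, base))
  eb <- expected_cell_rates(do.call(sim_config, off))
  pre <- ea$year < 2004
  expect_equal(ea$deaths[pre & ea$region == 1],
               eb$deaths[pre & eb$region == 1], tolerance = 1e-12)
  # the unscreened region is untouched throughout
  expect_equal(ea$deaths[ea$region == 2], eb$deaths[eb$region == 2],
               tolerance = 1e-12)
  # cumulative deaths fall in the screened region after rollout
  expect_lt(sum(ea$deaths[!pre & ea$region == 1]),
            sum(eb$deaths[!pre & eb$region == 1]))
})

test_that("rate-parameterised registries round-trip through tabulation", {
  sp <- lexis_spec()
  part <- partition_cells(sp)
  wy <- study_women_years(sp, part)
  sim <- simulate_rate_registry(sp, part, wy, study_death_rate,
                                background_ratio = 0.96, net_ratio = 0.85,
                                seed = 60)
  g <- tabulate_mortality(sim$records, sp)
  # every generated record passes the incidence-based filters
  expect_identical(sum(g$deaths), nrow(sim$records))
  expect_identical(sum(attr(g, "exclusions")), 0L)
  # scale sits near the study's totals
  rr_b <- region_contrast(build_lexis_grid(sim$records, wy, sp),
                          part, "too_old")
  expect_gt(rr_b$D0, 500); expect_lt(rr_b$D0, 900)
})
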