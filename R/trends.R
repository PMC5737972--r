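# Stage 2-4 incidence trends: 5-year attained-age and birth-cohort bands
# with Poisson annual-change fits, and year-specific age-matched MH ratios.

#' Build an attained-age trend band
#'
#' @param spec a [lexis_spec()].
#' @param age_range inclusive `(lower, upper)` completed ages.
#' @param years calendar years the band spans (default 2000--2007, the
#'   pre-rollout window of the second region).
#' @param label optional display label.
#' @return A `trend_band`: kind, label and member cells.
#' @export
age_band <- function(spec, age_range, years = 2000:2007, label = NULL) {
  cells <- lexis_cells(spec)
  cells <- cells[cells$age >= age_range[1] & cells$age <= age_range[2] &
                   cells$year %in% years, ]
  new_trend_band("attained_age",
                 label %||% paste0(age_range[1], "-", age_range[2]),
                 cells)
}

#' Build a birth-cohort (diagonal) trend band
#'
#' Members are the grid cells traversed, during `years`, by cohorts whose
#' age in `reference_year` lies in `cohort_range`; cells below the grid's
#' age floor are naturally excluded, so cohorts entering the grid mid-window
#' contribute only their in-grid years.
#'
#' @param spec a [lexis_spec()].
#' @param cohort_range inclusive `(lower, upper)` cohort ages in
#'   `reference_year`.
#' @param years calendar years the band spans.
#' @param reference_year year in which cohort age is expressed.
#' @param label optional display label.
#' @return A `trend_band`.
#' @export
cohort_band <- function(spec, cohort_range, years = 2000:2007,
                        reference_year = min(spec$years), label = NULL) {
  cells <- lexis_cells(spec)
  coh <- cells$age - (cells$year - reference_year)
  cells <- cells[coh >= cohort_range[1] & coh <= cohort_range[2] &
                   cells$year %in% years, ]
  new_trend_band("birth_cohort",
                 label %||% paste0("aged ", cohort_range[1], "-",
                                   cohort_range[2], " in ", reference_year),
                 cells)
}

new_trend_band <- function(kind, label, cells) {
  if (nrow(cells) == 0) stop("trend band '", label, "' is empty")
  rownames(cells) <- NULL
  structure(list(kind = kind, label = label,
                 cells = cells[c("age", "year")]),
            class = "trend_band")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trend_band <- function(x, ...) {
  cat("Trend band [", x$kind, "] ", x$label, ": ",
      nrow(x$cells), " cells, years ", min(x$cells$year), "-",
      max(x$cells$year), "\n", sep = "")
  invisible(x)
}

#' The seven default trend bands
#'
#' Three horizontal 5-year attained-age bands (50-54, 55-59, 60-64) and
#' four diagonal 5-cohort bands (aged 50-54, 55-59 and 60-64 in 2000, plus
#' the cohorts reaching age 50 in 2001-2005), all over the pre-rollout
#' years 2000-2007.  With the default grid the age bands cover 120 cells
#' and the diagonal bands 145; the 3 cells traversed by the cohorts
#' reaching age 50 in 2006 and 2007 belong to no band.
#'
#' @param spec a [lexis_spec()].
#' @param years band years (default 2000--2007 intersected with the grid).
#' @return Named list of seven `trend_band` objects.
#' @export
default_trend_bands <- function(spec,
                                years = intersect(2000:2007, spec$years)) {
  ref <- min(spec$years)
  list(
    age_50_54 = age_band(spec, c(50, 54), years),
    age_55_59 = age_band(spec, c(55, 59), years),
    age_60_64 = age_band(spec, c(60, 64), years),
    cohort_50_54 = cohort_band(spec, c(50, 54), years, ref),
    cohort_55_59 = cohort_band(spec, c(55, 59), years, ref),
    cohort_60_64 = cohort_band(spec, c(60, 64), years, ref),
    cohort_45_49 = cohort_band(spec, c(45, 49), years, ref,
                               label = paste("reached age 50 in",
                                             ref + 1, "-", ref + 5)))
}

#' Within-region annual change in stage 2-4 incidence along a band
#'
#' Fits a log-linear Poisson model,
#' `log E[count] = a + b * year + log(women_years)`, by maximum likelihood
#' over the band's cells in one region, and reports the slope as a percent
#' change per year, `100 * (exp(b) - 1)`.
#'
#' @param grid a [lexis_grid()] with person-time.
#' @param band a `trend_band`.
#' @param region region identifier.
#' @param events grid layer to model (default `"stage24_cases"`).
#' @return Percent change per year (scalar).
#' @export
band_annual_change <- function(grid, band, region,
                               events = "stage24_cases") {
  stopifnot(inherits(band, "trend_band"))
  sp <- grid_spec(grid)
  if (!region %in% sp$regions) stop("unknown region: ", region)
  sub <- grid[grid$region == region, ]
  i <- match(cell_id(band$cells$age, band$cells$year, region),
             cell_id(sub$age, sub$year, sub$region))
  if (anyNA(i)) stop("band refers to cells outside the grid")
  d <- sub[[events]][i]
  wy <- sub$women_years[i]
  year <- band$cells$year
  use <- !is.na(wy) & wy > 0
  if (length(unique(year[use])) < 2)
    stop("trend undefined: need person-time in at least 2 distinct years")
  if (sum(d[use]) == 0) stop("trend undefined: all counts are zero")
  dat <- data.frame(d = d[use], year = year[use], wy = wy[use])
  fit <- stats::glm(d ~ year + offset(log(wy)),
                    family = stats::poisson(), data = dat)
  if (!fit$converged)
    stop("Poisson trend fit did not converge after ", fit$iter,
         " IRLS iterations")
  100 * (exp(stats::coef(fit)[["year"]]) - 1)
}

#' Annual-change table over a set of bands and both regions
#'
#' @param grid a [lexis_grid()].
#' @param bands list of `trend_band`s (default [default_trend_bands()]).
#' @param events grid layer to model.
#' @return Data frame with one row per band x region: `kind`, `band`,
#'   `region`, `n_cells`, `pct_per_year`.
#' @export
band_trends <- function(grid, bands = NULL, events = "stage24_cases") {
  sp <- grid_spec(grid)
  bands <- bands %||% default_trend_bands(sp)
  rows <- lapply(bands, function(b) {
    data.frame(kind = b$kind, band = b$label, region = sp$regions,
               n_cells = nrow(b$cells),
               pct_per_year = vapply(sp$regions, function(r)
                 band_annual_change(grid, b, r, events), numeric(1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Year-specific age-matched Mantel-Haenszel rate ratios
#'
#' For each study year, summarises the between-region contrast over that
#' year's eligible cells with one stratum per attained age.  Years whose
#' eligible cells carry no events yield `NA` ("undefined") rows rather
#' than errors.
#'
#' @param grid a [lexis_grid()] with person-time.
#' @param partition an eligibility partition on the same spec.
#' @param events grid layer to contrast (default `"stage24_cases"`).
#' @return Data frame with one row per year: `year`, `estimate`, `lcl`,
#'   `ucl`, `D1`, `D0`, `n_strata`.
#' @export
yearly_mh_ratios <- function(grid, partition, events = "stage24_cases") {
  sp <- grid_spec(grid)
  events <- match.arg(events, c("stage24_cases", "deaths"))
  strata <- contrast_strata(grid, partition, "eligible", events)
  out <- lapply(sp$years, function(y) {
    s <- strata[strata$year == y, ]
    if (nrow(s) == 0 || sum(s$d1 + s$d0) == 0)
      return(data.frame(year = y, estimate = NA_real_, lcl = NA_real_,
                        ucl = NA_real_, D1 = sum(s$d1), D0 = sum(s$d0),
                        n_strata = 0L))
    rr <- mh_rate_ratio(s$d1, s$t1, s$d0, s$t0)
    data.frame(year = y, estimate = rr$estimate, lcl = rr$ci95[1],
               ucl = rr$ci95[2], D1 = rr$D1, D0 = rr$D0,
               n_strata = rr$n_strata)
  })
  do.call(rbind, out)
}
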