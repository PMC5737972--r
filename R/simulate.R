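# Synthetic cancer registries.
#
# Two generators:
#  * simulate_registry(): a mechanistic microsimulation of two regions with
#    staggered programme starts -- women follow their cohort diagonals, may
#    be clinically diagnosed, participating invitees have diagnoses within
#    the lead time advanced to the invitation year (with a stage shift to
#    stage 1), and post-diagnosis survival depends on recorded stage.  Net
#    effects here are emergent, not dialled in.
#  * simulate_rate_registry() / simulate_stage24_grid(): direct
#    rate-parameterised generators in which the background and net rate
#    ratios are explicit parameters, for estimator-calibration studies with
#    a known truth.
# expected_cell_rates() computes the microsimulation's per-cell expectations
# in closed form (no sampling) and serves as its analytic oracle.

#' Configuration for the registry microsimulation
#'
#' Defaults describe a two-region programme rollout on the default grid:
#' biennial invitations at ages 50-64 starting 2000 (region 1) and 2008
#' (region 2), 70% fixed per-woman participation, a mean screening lead
#' time of 2 years, and a 50% chance that a screen-detected cancer is
#' recorded at stage 1 instead of stage 2-4.  Case fatality after diagnosis
#' is a constant per-year hazard, far higher for stage 2-4 than stage 1, so
#' the stage shift is what generates the delayed mortality benefit.
#'
#' @param spec a [lexis_spec()]; the grid the output is tabulated onto.
#' @param cohort_size women per 1-year birth cohort per region (scalar), or
#'   a data frame `region`, `cohort_age`, `n` for unequal cohorts.
#' @param cohort_ages cohort ages in the reference year to simulate
#'   (default: every cohort that ever enters the grid).
#' @param baseline_hazard function of age giving the per-woman-year clinical
#'   breast-cancer diagnosis hazard.
#' @param stage24_fraction probability a clinical diagnosis is stage 2-4.
#' @param schedules list of two [invitation_schedule()]s, one per region in
#'   spec order.
#' @param participation fixed per-woman probability of being an attender
#'   (a latent trait, not re-drawn each round).
#' @param lead_mean mean of the Poisson-distributed whole-year lead time by
#'   which screen detection can advance a diagnosis.
#' @param stage_shift probability that a screen-detected cancer that would
#'   have been stage 2-4 is recorded at stage 1.
#' @param fatality named per-year breast-cancer death hazards after
#'   diagnosis, `c(stage1 = ..., stage2_4 = ...)`.
#' @param other_cause_hazard per-year hazard of death from other causes
#'   (default 0: person-time ends at breast-cancer death or study end).
#' @param followup_end last simulated calendar year (default: last grid
#'   year).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(spec = lexis_spec(),
                       cohort_size = 6000L,
                       cohort_ages = NULL,
                       baseline_hazard = function(age)
                         2.4e-3 + 2.0e-5 * pmax(age - 50, 0),
                       stage24_fraction = 0.55,
                       schedules = list(
                         invitation_schedule(2000L),
                         invitation_schedule(2008L)),
                       participation = 0.70,
                       lead_mean = 2,
                       stage_shift = 0.5,
                       fatality = c(stage1 = 0.015, stage2_4 = 0.08),
                       other_cause_hazard = 0,
                       followup_end = NULL) {
  ref <- min(spec$years)
  cohort_ages <- cohort_ages %||%
    seq.int(min(spec$ages) - (max(spec$years) - ref), max(spec$ages))
  cfg <- structure(list(spec = spec,
                        cohort_size = cohort_size,
                        cohort_ages = as.integer(cohort_ages),
                        baseline_hazard = baseline_hazard,
                        stage24_fraction = stage24_fraction,
                        schedules = schedules,
                        participation = participation,
                        lead_mean = lead_mean,
                        stage_shift = stage_shift,
                        fatality = fatality,
                        other_cause_hazard = other_cause_hazard,
                        followup_end = followup_end %||% max(spec$years),
                        reference_year = ref),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config a [sim_config()].
#' @return The config, invisibly; errors on the first violated invariant.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  frac <- c(participation = config$participation,
            stage24_fraction = config$stage24_fraction,
            stage_shift = config$stage_shift)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    stop("fractions must lie in [0, 1]: ",
         paste(names(frac)[bad], collapse = ", "))
  if (!is.function(config$baseline_hazard))
    stop("'baseline_hazard' must be a function of age")
  h <- config$baseline_hazard(config$spec$ages)
  if (any(h < 0 | h > 1)) stop("'baseline_hazard' must map into [0, 1]")
  if (!all(c("stage1", "stage2_4") %in% names(config$fatality)))
    stop("'fatality' needs named elements 'stage1' and 'stage2_4'")
  if (any(config$fatality < 0 | config$fatality > 1))
    stop("'fatality' hazards must lie in [0, 1]")
  if (config$lead_mean < 0) stop("'lead_mean' must be >= 0")
  if (config$other_cause_hazard < 0 || config$other_cause_hazard >= 1)
    stop("'other_cause_hazard' must lie in [0, 1)")
  if (length(config$schedules) != 2 ||
      !all(vapply(config$schedules, inherits, logical(1),
                  "invitation_schedule")))
    stop("'schedules' must be a list of two invitation_schedule objects")
  for (s in config$schedules) {
    if (s$reference_year != config$reference_year)
      stop("schedule reference year must match the grid's first year")
    if (s$first_round_year < config$reference_year)
      stop("programme starts before the study window are not supported")
  }
  if (config$followup_end < config$reference_year)
    stop("'followup_end' precedes the study start")
  invisible(config)
}

# one row per (region index, cohort age) with its size
cohort_table <- function(config) {
  if (is.data.frame(config$cohort_size)) {
    cs <- config$cohort_size
    if (!all(c("region", "cohort_age", "n") %in% names(cs)))
      stop("cohort_size data frame needs columns region, cohort_age, n")
    ridx <- match(cs$region, config$spec$regions)
    if (anyNA(ridx)) stop("cohort_size table has unknown regions")
    return(data.frame(region_idx = ridx, cohort_age = cs$cohort_age,
                      n = as.integer(cs$n)))
  }
  expand.grid(region_idx = c(1L, 2L),
              cohort_age = config$cohort_ages,
              KEEP.OUT.ATTRS = FALSE) |>
    transform(n = as.integer(config$cohort_size))
}

# invitation calendar years for one (region index, cohort age)
invitation_years <- function(config, region_idx, cohort_age) {
  sch <- config$schedules[[region_idx]]
  ages <- invitation_ages(cohort_age, sch)
  sch$reference_year + (ages - cohort_age)
}

#' Simulate a synthetic cancer registry
#'
#' Runs the microsimulation described in [sim_config()]: each woman follows
#' her cohort diagonal from the study start; each year she may be
#' clinically diagnosed; a participating woman invited in year r has any
#' clinical diagnosis falling within her lead time after r advanced to r
#' (detected at the first screen at which it is detectable), with a
#' stage-shift chance of being recorded stage 1; survival after the
#' recorded diagnosis follows the stage-specific case-fatality hazard on a
#' whole-year clock.  Identical config and seed give byte-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return List with `records` (a `registry_records` data frame, one row
#'   per diagnosed woman) and `women_years` (per-cell denominator table;
#'   a woman contributes person-time through her death year inclusive).
#' @export
simulate_registry <- function(config, seed) {
  validate_sim_config(config)
  set.seed(seed)
  spec <- config$spec
  ref <- config$reference_year
  end <- config$followup_end
  ny <- end - ref + 1L
  ct <- cohort_table(config)
  N <- sum(ct$n)
  gid <- rep(seq_len(nrow(ct)), ct$n)
  region_idx <- ct$region_idx[gid]
  cohort_age <- ct$cohort_age[gid]

  # clinical (no-screening) diagnosis year
  dxc <- rep(NA_integer_, N)
  undx <- rep(TRUE, N)
  for (y in ref:end) {
    h <- pmin(pmax(config$baseline_hazard(cohort_age + (y - ref)), 0), 1)
    idx <- which(undx)
    hit <- idx[stats::runif(length(idx)) < h[idx]]
    dxc[hit] <- y
    undx[hit] <- FALSE
  }
  participant <- stats::runif(N) < config$participation
  od <- if (config$other_cause_hazard > 0)
    ref + stats::rgeom(N, config$other_cause_hazard)
  else rep(Inf, N)

  D <- which(!is.na(dxc))
  nD <- length(D)
  lead <- stats::rpois(nD, config$lead_mean)
  stage24_base <- stats::runif(nD) < config$stage24_fraction
  shift_draw <- stats::runif(nD) < config$stage_shift

  # screen detection: earliest invitation at which the cancer is within
  # its lead time of clinical surfacing
  det <- rep(NA_integer_, nD)
  dxD <- dxc[D]
  partD <- participant[D]
  by_group <- split(seq_len(nD), gid[D])
  for (g in names(by_group)) {
    gi <- as.integer(g)
    inv <- invitation_years(config, ct$region_idx[gi], ct$cohort_age[gi])
    m <- by_group[[g]]
    for (r in inv) {
      ok <- is.na(det[m]) & partD[m] & dxD[m] >= r & dxD[m] - lead[m] <= r
      det[m[ok]] <- r
    }
  }
  detected <- !is.na(det)
  dx_rec <- ifelse(detected, det, dxD)
  stage <- ifelse(stage24_base & !(detected & shift_draw),
                  "stage2_4", "stage1")
  q <- unname(config$fatality[ifelse(stage == "stage2_4",
                                     "stage2_4", "stage1")])
  death_bc <- dx_rec + stats::rgeom(nD, q)
  odD <- od[D]
  recorded <- dx_rec <= odD
  bc_first <- death_bc <= pmin(end, odD)
  death_year <- ifelse(bc_first, death_bc,
                       ifelse(odD <= end, odD, NA_real_))
  death_cause <- ifelse(bc_first, "breast_cancer",
                        ifelse(odD <= end, "other", NA_character_))

  rec <- data.frame(
    region = spec$regions[region_idx[D][recorded]],
    year_dx = dx_rec[recorded],
    age_dx = cohort_age[D][recorded] + dx_rec[recorded] - ref,
    stage_class = stage[recorded],
    death_year = as.integer(death_year[recorded]),
    death_cause = death_cause[recorded],
    stringsAsFactors = FALSE)
  records <- as_registry_records(rec)

  # person-time: every woman contributes through her death year inclusive
  death_any <- od
  death_any[D] <- pmin(odD, ifelse(recorded, death_bc, Inf))
  wy <- vector("list", nrow(ct))
  for (gi in seq_len(nrow(ct))) {
    members <- which(gid == gi)
    da <- death_any[members]
    dy <- da[is.finite(da) & da <= end]
    tb <- if (length(dy) > 0) tabulate(dy - ref + 1L, nbins = ny)
    else integer(ny)
    alive <- ct$n[gi] - c(0L, cumsum(tb))[seq_len(ny)]
    ages <- ct$cohort_age[gi] + 0:(ny - 1L)
    keep <- ages %in% spec$ages & (ref:end) %in% spec$years
    if (!any(keep)) next
    wy[[gi]] <- data.frame(age = ages[keep], year = (ref:end)[keep],
                           region = spec$regions[ct$region_idx[gi]],
                           women_years = as.numeric(alive[keep]))
  }
  wy <- do.call(rbind, wy)
  wy <- stats::aggregate(women_years ~ age + year + region, wy, sum)
  list(records = records, women_years = wy)
}

#' Expected per-cell rates under the microsimulation mechanism
#'
#' Deterministic computation of each Lexis cell's expected stage 1 and
#' stage 2-4 case counts, incidence-based breast-cancer deaths and
#' women-years under the same mechanism as [simulate_registry()] (summing
#' over the lead-time distribution instead of sampling).  The mortality
#' filters mirror [tabulate_mortality()] so the output is directly
#' comparable to a tabulated simulated grid.
#'
#' @param config a [sim_config()].
#' @param dx_age_min youngest diagnosis age whose deaths are counted
#'   (default 50, as in [tabulate_mortality()]).
#' @param death_age_range inclusive death-age window (default `c(50, 84)`).
#' @return Data frame with one row per in-grid (region, age, year) cell:
#'   `cases_stage1`, `cases_stage24`, `deaths`, `women_years`.
#' @export
expected_cell_rates <- function(config, dx_age_min = 50L,
                                death_age_range = c(50L, 84L)) {
  validate_sim_config(config)
  spec <- config$spec
  ref <- config$reference_year
  end <- config$followup_end
  ny <- end - ref + 1L
  years <- ref:end
  ct <- cohort_table(config)
  p <- config$participation
  f24 <- config$stage24_fraction
  shift <- config$stage_shift
  hoc <- config$other_cause_hazard
  Po <- (1 - hoc)^(years - ref)            # P(other-cause death >= year)

  # Poisson lead-time pmf with the upper tail lumped into the last bin
  # (detection saturates there, so the lumping is exact)
  lmax <- ny
  pl <- c(stats::dpois(0:(lmax - 1), config$lead_mean),
          stats::ppois(lmax - 1, config$lead_mean, lower.tail = FALSE))
  ells <- 0:lmax

  out <- vector("list", nrow(ct))
  for (gi in seq_len(nrow(ct))) {
    ca <- ct$cohort_age[gi]
    n <- ct$n[gi]
    ages <- ca + 0:(ny - 1L)
    h <- pmin(pmax(config$baseline_hazard(ages), 0), 1)
    S <- c(1, cumprod(1 - h))[seq_len(ny)]
    pdx <- S * h                           # P(clinical diagnosis in year t)
    inv <- invitation_years(config, ct$region_idx[gi], ca)

    rec1 <- numeric(ny)                    # recorded-diagnosis mass by year
    rec24 <- numeric(ny)
    for (ti in seq_len(ny)) {
      w <- pdx[ti]
      if (w == 0) next
      t <- years[ti]
      rec24[ti] <- rec24[ti] + (1 - p) * w * f24
      rec1[ti] <- rec1[ti] + (1 - p) * w * (1 - f24)
      if (p == 0) next
      if (length(inv) == 0) {
        rec24[ti] <- rec24[ti] + p * w * f24
        rec1[ti] <- rec1[ti] + p * w * (1 - f24)
        next
      }
      for (li in seq_along(ells)) {
        wl <- p * w * pl[li]
        if (wl == 0) next
        cand <- inv[inv >= t - ells[li] & inv <= t]
        if (length(cand) == 0) {
          rec24[ti] <- rec24[ti] + wl * f24
          rec1[ti] <- rec1[ti] + wl * (1 - f24)
        } else {
          ri <- min(cand) - ref + 1L
          rec24[ri] <- rec24[ri] + wl * f24 * (1 - shift)
          rec1[ri] <- rec1[ri] + wl * ((1 - f24) + f24 * shift)
        }
      }
    }

    # deaths: stage-specific geometric survival from the recorded year
    pbc <- numeric(ny)                     # P(bc death in year), uncensored
    edeath <- numeric(ny)                  # expected *counted* deaths
    for (ri in seq_len(ny)) {
      for (sname in c("stage1", "stage2_4")) {
        m <- if (sname == "stage1") rec1[ri] else rec24[ri]
        if (m == 0) next
        q <- unname(config$fatality[sname])
        if (q == 0) next
        g <- 0:(ny - ri)
        pd <- m * q * (1 - q)^g
        di <- ri + g
        pbc[di] <- pbc[di] + pd
        if (ages[ri] >= dx_age_min) {
          dage <- ca + di - 1L
          okd <- dage >= death_age_range[1] & dage <= death_age_range[2] &
            dage %in% spec$ages
          edeath[di[okd]] <- edeath[di[okd]] + (pd * Po[di])[okd]
        }
      }
    }

    alive <- (1 - c(0, cumsum(pbc))[seq_len(ny)]) * Po
    keep <- ages %in% spec$ages
    if (!any(keep)) next
    out[[gi]] <- data.frame(
      region = spec$regions[ct$region_idx[gi]],
      age = ages[keep], year = years[keep],
      cases_stage1 = n * (rec1 * Po)[keep],
      cases_stage24 = n * (rec24 * Po)[keep],
      deaths = n * edeath[keep],
      women_years = n * alive[keep])
  }
  out <- do.call(rbind, out)
  out <- stats::aggregate(
    cbind(cases_stage1, cases_stage24, deaths, women_years) ~
      region + age + year, out, sum)
  out[order(out$region, out$year, out$age), , drop = FALSE]
}

# normalise a rate spec (scalar, f(age), f(age, year)) to f(age, year)
as_rate_fun <- function(rate) {
  if (!is.function(rate))
    return(function(age, year) rep_len(rate, length(age)))
  if (length(formals(rate)) >= 2) rate
  else function(age, year) rate(age)
}

#' Uniform per-cell person-time table
#'
#' @param spec a [lexis_spec()].
#' @param per_cell women-years per cell, one value per region (recycled).
#' @return Data frame `age`, `year`, `region`, `women_years` covering the
#'   grid.
#' @export
uniform_women_years <- function(spec, per_cell) {
  per_cell <- rep_len(per_cell, 2L)
  df <- expand.grid(age = spec$ages, year = spec$years,
                    region = spec$regions, KEEP.OUT.ATTRS = FALSE)
  df$women_years <- per_cell[match(df$region, spec$regions)]
  df
}

#' Simulate registry death records under explicit rate ratios
#'
#' Direct rate-parameterised generator for estimator calibration: cell
#' death counts are Poisson with reference-region rate `death_rate(age)`,
#' multiplied in the index region by `background_ratio` everywhere and
#' additionally by `net_ratio` in the screening-eligible cells.  Each death
#' is expanded into a registry record whose diagnosis year is drawn a few
#' years before death (respecting the incidence-based filters), so the
#' records round-trip exactly through [tabulate_mortality()].
#'
#' @param spec a [lexis_spec()].
#' @param partition an eligibility partition on the same spec.
#' @param women_years per-cell denominator table (e.g.
#'   [uniform_women_years()]).
#' @param death_rate deaths per woman-year: scalar, function of age, or
#'   function of (age, year).
#' @param background_ratio index/reference rate ratio shared by all cells.
#' @param net_ratio additional index-region ratio in eligible cells (the
#'   known truth a double difference should recover).
#' @param dx_lag_max maximum years between diagnosis and death in the
#'   generated records.
#' @param death_age_range inclusive death-age window: cells outside it get
#'   no deaths, mirroring the mortality tabulation's default filters.
#' @param seed optional RNG seed.
#' @return List with `records` and `women_years`, as
#'   [simulate_registry()].
#' @export
simulate_rate_registry <- function(spec, partition, women_years,
                                   death_rate, background_ratio = 1,
                                   net_ratio = 1, dx_lag_max = 4L,
                                   death_age_range = c(50L, 84L),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate_fun <- as_rate_fun(death_rate)
  wy <- as.data.frame(women_years)
  i <- match(cell_id(wy$age, wy$year, NA), cell_id(partition$age,
                                                   partition$year, NA))
  if (anyNA(i)) stop("person-time table has cells outside the partition")
  eligible <- partition$label[i] == "eligible"
  index <- wy$region == spec$regions[1]
  lambda <- rate_fun(wy$age, wy$year) * wy$women_years *
    ifelse(index, background_ratio, 1) *
    ifelse(index & eligible, net_ratio, 1)
  lambda[wy$age < death_age_range[1] | wy$age > death_age_range[2]] <- 0
  d <- stats::rpois(nrow(wy), lambda)
  pos <- d > 0
  cell <- wy[rep(which(pos), d[pos]), c("age", "year", "region")]
  lag_cap <- pmin(dx_lag_max, cell$year - min(spec$years), cell$age - 50L)
  lag_cap <- pmax(lag_cap, 0L)
  u <- floor(stats::runif(nrow(cell)) * (lag_cap + 1))
  rec <- data.frame(region = cell$region,
                    year_dx = cell$year - u,
                    age_dx = cell$age - u,
                    stage_class = "stage2_4",
                    death_year = cell$year,
                    death_cause = "breast_cancer",
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  list(records = as_registry_records(rec), women_years = wy)
}

#' Simulate a stage 2-4 grid under a known net-deficit model
#'
#' Generates per-cell Poisson stage 2-4 counts with reference-region rate
#' `base_rate(age)`, index-region multiplier `background_ratio`, and, in
#' eligible cells, the additional net ratio
#' `exp(b0 + b1 yc + b2 yc^2)` implied by `coef` on year centred at
#' `year_center` -- the data-generating model that [netfit()] should
#' recover.
#'
#' @param spec a [lexis_spec()].
#' @param partition an eligibility partition on the same spec.
#' @param women_years per-cell denominator table.
#' @param base_rate cases per woman-year: scalar, function of age, or
#'   function of (age, year).
#' @param background_ratio index/reference background rate ratio.
#' @param coef numeric vector of 1-3 coefficients `(b0, b1, b2)` of the
#'   log net ratio.
#' @param year_center centring year (default: study midpoint).
#' @param seed optional RNG seed.
#' @return A [lexis_grid()] with `stage24_cases` and `women_years` filled.
#' @export
simulate_stage24_grid <- function(spec, partition, women_years, base_rate,
                                  background_ratio = 1, coef = 0,
                                  year_center = mean(range(spec$years)),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate_fun <- as_rate_fun(base_rate)
  wy <- as.data.frame(women_years)
  i <- match(cell_id(wy$age, wy$year, NA),
             cell_id(partition$age, partition$year, NA))
  if (anyNA(i)) stop("person-time table has cells outside the partition")
  eligible <- partition$label[i] == "eligible"
  index <- wy$region == spec$regions[1]
  basis <- c("constant", "linear", "quadratic")[length(coef)]
  lognet <- drop(time_basis(wy$year, year_center, basis) %*% coef)
  lambda <- rate_fun(wy$age, wy$year) * wy$women_years *
    ifelse(index, background_ratio, 1) *
    ifelse(index & eligible, exp(lognet), 1)
  counts <- wy[c("age", "year", "region")]
  counts$stage24_cases <- stats::rpois(nrow(wy), lambda)
  lexis_grid(spec, stage24_cases = counts, women_years = wy)
}
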