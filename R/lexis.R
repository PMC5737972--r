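# Lexis-grid geometry: cells, cohorts, eligibility polygons, invitation
# schedules and the 3x3 neighbourhood smoother used for display surfaces.

#' Define a Lexis grid specification
#'
#' A Lexis grid is a rectangle of 1-year x 1-year (age, calendar-year) cells.
#' Ages are completed years at the start of the calendar year, so a cell
#' `(a, y)` covers `[a, a+1) x [y, y+1)` and a birth cohort travels along the
#' diagonal with constant cohort index `c = y - a`.
#'
#' @param ages integer vector of consecutive completed ages (default 50--85,
#'   36 ages).
#' @param years integer vector of consecutive calendar years (default
#'   2000--2013, 14 years).
#' @param regions length-2 vector of region identifiers; the first is the
#'   "index" region (earlier screening start) in all contrasts.
#' @return An object of class `lexis_spec`.
#' @examples
#' sp <- lexis_spec()
#' nrow(lexis_cells(sp))  # 36 * 14 = 504
#' @export
lexis_spec <- function(ages = 50:85, years = 2000:2013, regions = c(1L, 2L)) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (length(ages) == 0L || length(years) == 0L)
    stop("'ages' and 'years' must be non-empty")
  if (anyNA(ages) || anyNA(years))
    stop("'ages' and 'years' must not contain NA")
  if (length(ages) > 1L && any(diff(ages) != 1L))
    stop("'ages' must be consecutive integers")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("'years' must be consecutive integers")
  if (any(ages < 0L)) stop("ages must be non-negative")
  if (length(regions) != 2L) stop("exactly two regions are supported")
  if (anyDuplicated(regions)) stop("region identifiers must be distinct")
  structure(list(ages = ages, years = years, regions = regions),
            class = "lexis_spec")
}

#' @export
print.lexis_spec <- function(x, ...) {
  cat("Lexis grid specification\n")
  cat("  ages:    ", min(x$ages), "-", max(x$ages),
      " (", length(x$ages), " ages)\n", sep = "")
  cat("  years:   ", min(x$years), "-", max(x$years),
      " (", length(x$years), " years)\n", sep = "")
  cat("  regions: ", paste(x$regions, collapse = ", "),
      " (index region: ", x$regions[1], ")\n", sep = "")
  invisible(x)
}

#' Enumerate the cells of a Lexis grid
#'
#' @param spec a [lexis_spec()].
#' @return A data frame with columns `age` and `year`, one row per cell,
#'   ordered year-major.
#' @export
lexis_cells <- function(spec) {
  stopifnot(inherits(spec, "lexis_spec"))
  expand.grid(age = spec$ages, year = spec$years, KEEP.OUT.ATTRS = FALSE)
}

#' Partition Lexis cells into screening-eligible and too-old polygons
#'
#' Classifies every cell by the age its cohort had in a reference year:
#' cohorts aged at most `cutoff` in `reference_year` could be invited to
#' screening at some point ("eligible", the lower polygon); older cohorts
#' never could ("too_old", the upper polygon, which identifies background
#' between-region differences).  With the default 36 x 14 grid and cutoff 64
#' in 2000 the split is 301 eligible and 203 too-old cells.
#'
#' @param spec a [lexis_spec()].
#' @param cutoff maximum age in `reference_year` for eligibility (default 64).
#' @param reference_year year at which cohort age is evaluated; must lie in
#'   the grid's year range (default: first grid year).
#' @return An object of class `eligibility_partition`: a data frame with
#'   columns `age`, `year`, `label` (factor `eligible`/`too_old`), carrying
#'   the rule as attributes.
#' @examples
#' p <- partition_cells(lexis_spec())
#' table(p$label)  # 301 eligible, 203 too_old
#' @export
partition_cells <- function(spec, cutoff = 64L,
                            reference_year = min(spec$years)) {
  stopifnot(inherits(spec, "lexis_spec"))
  reference_year <- as.integer(reference_year)
  if (!reference_year %in% spec$years)
    stop("'reference_year' (", reference_year, ") lies outside the grid years")
  cells <- lexis_cells(spec)
  age_at_ref <- cells$age - (cells$year - reference_year)
  cells$label <- factor(ifelse(age_at_ref <= cutoff, "eligible", "too_old"),
                        levels = c("eligible", "too_old"))
  structure(cells,
            cutoff = as.integer(cutoff),
            reference_year = reference_year,
            class = c("eligibility_partition", "data.frame"))
}

#' @export
print.eligibility_partition <- function(x, ...) {
  n <- table(x$label)
  cat("Eligibility partition (cohort age <= ", attr(x, "cutoff"), " in ",
      attr(x, "reference_year"), ")\n", sep = "")
  cat("  eligible cells: ", n[["eligible"]], "\n", sep = "")
  cat("  too-old cells:  ", n[["too_old"]], "\n", sep = "")
  cat("  total:          ", nrow(x), "\n", sep = "")
  invisible(x)
}

#' Describe a region's screening invitation schedule
#'
#' Rounds run every `interval` years from `first_round_year`, inviting women
#' whose completed age lies in `age_window`.  Cohorts still under the lower
#' age bound at programme start are first invited in the calendar year they
#' reach it, and follow their own biennial clock thereafter.
#'
#' @param first_round_year calendar year of the first invitation round.
#' @param interval years between a woman's successive invitations (default 2).
#' @param age_window inclusive `(lower, upper)` ages for invitation
#'   (default `c(50, 64)`).
#' @param last_followup_year no invitations are issued after this year
#'   (default 2013).
#' @param reference_year year in which cohort ages are expressed
#'   (default 2000).
#' @return An object of class `invitation_schedule`.
#' @export
invitation_schedule <- function(first_round_year, interval = 2L,
                                age_window = c(50L, 64L),
                                last_followup_year = 2013L,
                                reference_year = 2000L) {
  interval <- as.integer(interval)
  age_window <- as.integer(age_window)
  if (interval < 1L) stop("'interval' must be >= 1")
  if (length(age_window) != 2L || age_window[1] > age_window[2])
    stop("'age_window' must be (lower, upper) with lower <= upper")
  structure(list(first_round_year = as.integer(first_round_year),
                 interval = interval,
                 age_window = age_window,
                 last_followup_year = as.integer(last_followup_year),
                 reference_year = as.integer(reference_year)),
            class = "invitation_schedule")
}

#' @export
print.invitation_schedule <- function(x, ...) {
  cat("Invitation schedule: first round ", x$first_round_year,
      ", every ", x$interval, " years, ages ",
      x$age_window[1], "-", x$age_window[2],
      ", follow-up through ", x$last_followup_year, "\n", sep = "")
  invisible(x)
}

#' Ages at which one birth cohort is invited to screening
#'
#' @param cohort_age the cohort's completed age in the schedule's reference
#'   year (>= 0).
#' @param schedule an [invitation_schedule()].
#' @return Integer vector of ages at invitation (possibly empty), strictly
#'   increasing and spaced by at least the schedule interval.
#' @examples
#' # a cohort aged 54 in 2000 under a programme starting in 2008 is
#' # invited twice, at ages 62 and 64
#' invitation_ages(54, invitation_schedule(2008))
#' @export
invitation_ages <- function(cohort_age, schedule) {
  stopifnot(inherits(schedule, "invitation_schedule"))
  cohort_age <- as.integer(cohort_age)
  if (length(cohort_age) != 1L || is.na(cohort_age) || cohort_age < 0L)
    stop("'cohort_age' must be a single non-negative integer")
  lo <- schedule$age_window[1]
  hi <- schedule$age_window[2]
  age_at_first <- cohort_age + (schedule$first_round_year -
                                  schedule$reference_year)
  # cohorts below the window at programme start enter the year they reach it
  start <- if (age_at_first < lo)
    schedule$reference_year + (lo - cohort_age)
  else
    schedule$first_round_year
  if (start > schedule$last_followup_year) return(integer(0))
  rounds <- seq.int(start, schedule$last_followup_year,
                    by = schedule$interval)
  ages <- cohort_age + (rounds - schedule$reference_year)
  ages[ages >= lo & ages <= hi]
}

#' Invitation counts across a range of cohorts
#'
#' @param cohort_ages vector of cohort ages in the reference year.
#' @param schedule an [invitation_schedule()].
#' @return Named integer vector of invitation counts, one per cohort.
#' @export
invitation_counts <- function(cohort_ages, schedule) {
  n <- vapply(cohort_ages,
              function(a) length(invitation_ages(a, schedule)),
              integer(1))
  names(n) <- cohort_ages
  n
}

#' Smooth a count surface by truncated 3x3 window means
#'
#' Replaces each cell with the arithmetic mean of the cells in the 3x3
#' square centred on it, intersected with the grid (edge windows are
#' truncated rather than padded, so no values outside the grid are
#' invented).  Intended for de-noising sparse death surfaces for display.
#'
#' @param x numeric matrix (ages in rows, years in columns, or any
#'   rectangular layout).
#' @return Matrix of the same shape; every output value lies within the
#'   range of the inputs.
#' @export
smooth_3x3 <- function(x) {
  if (!is.matrix(x) || length(x) == 0L)
    stop("'x' must be a non-empty matrix")
  if (!is.numeric(x)) stop("'x' must be numeric")
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc, dimnames = dimnames(x))
  for (i in seq_len(nr)) {
    ri <- max(1L, i - 1L):min(nr, i + 1L)
    for (j in seq_len(nc)) {
      cj <- max(1L, j - 1L):min(nc, j + 1L)
      out[i, j] <- mean(x[ri, cj])
    }
  }
  out
}
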