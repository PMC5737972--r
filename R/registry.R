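# Registry-style incidence files: one row per diagnosed woman, linked to a
# death certificate where one exists, and their tabulation onto a LexisGrid.

REGISTRY_COLUMNS <- c("region", "year_dx", "age_dx", "stage_class",
                      "death_year", "death_cause")
STAGE_LEVELS <- c("stage1", "stage2_4", "unknown")
CAUSE_LEVELS <- c("breast_cancer", "other")

#' Read a registry incidence file
#'
#' Parses a delimited text file (comma- or tab-separated, autodetected from
#' the `.tsv`/`.txt` extension) with one row per diagnosed woman.  Canonical
#' columns are `region`, `year_dx`, `age_dx`, `stage_class`
#' (`stage1`/`stage2_4`/`unknown`), `death_year` and `death_cause`
#' (`breast_cancer`/`other`); the last two may be empty for women alive at
#' the end of follow-up.  Rows violating the record invariants (death before
#' diagnosis, unknown stage label, a cause without a death year, ...) are
#' rejected individually with line-level diagnostics rather than aborting
#' the whole read.
#'
#' @param path file to read.
#' @param config optional column mapping: either a named list/vector mapping
#'   canonical names to file column names, or the path of a YAML file of
#'   `canonical: actual` pairs.
#' @return A `registry_records` data frame of the accepted rows, with the
#'   rejected rows (line number and reason) in attribute `"rejected"`.
#' @export
read_registry <- function(path, config = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           na.strings = c("NA", ""),
                           check.names = FALSE, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  map <- stats::setNames(REGISTRY_COLUMNS, REGISTRY_COLUMNS)
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1 && file.exists(config))
      config <- yaml::read_yaml(config)
    config <- unlist(config)
    bad <- setdiff(names(config), REGISTRY_COLUMNS)
    if (length(bad) > 0)
      stop("unknown canonical column(s) in mapping: ",
           paste(bad, collapse = ", "))
    map[names(config)] <- config
  }
  miss <- map[!map %in% names(raw)]
  if (length(miss) > 0)
    stop("registry file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  raw <- raw[, map, drop = FALSE]
  names(raw) <- REGISTRY_COLUMNS
  parse_registry_rows(raw)
}

as_int <- function(x) suppressWarnings(as.integer(x))

parse_registry_rows <- function(raw) {
  n <- nrow(raw)
  reason <- character(n)
  flag <- function(bad, why) {
    new <- bad & !nzchar(reason)
    reason[new] <<- why
  }
  region <- as_int(raw$region)
  year_dx <- as_int(raw$year_dx)
  age_dx <- as_int(raw$age_dx)
  stage <- raw$stage_class
  death_year <- as_int(raw$death_year)
  cause <- raw$death_cause

  flag(is.na(region), "unparseable region")
  flag(is.na(year_dx), "unparseable year_dx")
  flag(is.na(age_dx), "unparseable age_dx")
  flag(!is.na(age_dx) & age_dx < 0, "negative age_dx")
  flag(is.na(stage) | !stage %in% STAGE_LEVELS, "invalid stage_class")
  flag(!is.na(raw$death_year) & is.na(death_year), "unparseable death_year")
  flag(!is.na(cause) & !cause %in% CAUSE_LEVELS, "invalid death_cause")
  flag(!is.na(cause) & is.na(raw$death_year),
       "death_cause present without death_year")
  flag(!is.na(death_year) & !is.na(year_dx) & death_year < year_dx,
       "death_year before year_dx")

  bad <- nzchar(reason)
  rejected <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                         reason = reason[bad],
                         stringsAsFactors = FALSE)
  rec <- data.frame(region = region, year_dx = year_dx, age_dx = age_dx,
                    stage_class = stage, death_year = death_year,
                    death_cause = cause,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  if (nrow(rejected) > 0)
    message("read_registry: rejected ", nrow(rejected), " of ", n, " rows")
  structure(rec, rejected = rejected,
            class = c("registry_records", "data.frame"))
}

#' Coerce a data frame of diagnoses to registry records
#'
#' Applies the same row-level validation as [read_registry()] to an
#' in-memory data frame (as produced, e.g., by the simulator).
#'
#' @param df data frame with the canonical registry columns.
#' @return A `registry_records` data frame.
#' @export
as_registry_records <- function(df) {
  if (inherits(df, "registry_records")) return(df)
  miss <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(miss) > 0)
    stop("missing registry column(s): ", paste(miss, collapse = ", "))
  raw <- data.frame(lapply(df[REGISTRY_COLUMNS], as.character),
                    stringsAsFactors = FALSE)
  parse_registry_rows(raw)
}

#' Write registry records to a delimited text file
#'
#' @param records a `registry_records` data frame.
#' @param path output path; `.tsv`/`.txt` extension writes tab-separated,
#'   anything else comma-separated.  Missing death fields are written empty.
#' @export
write_registry <- function(records, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(records), path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Tabulate incidence-based breast-cancer deaths onto a Lexis grid
#'
#' Implements the incidence-based mortality rule: a death enters the cell
#' (age at death, year of death) of its region only if it was certified as
#' breast cancer **and** the underlying cancer was diagnosed inside the
#' evaluation window (diagnosis year at or after the programme start,
#' diagnosis age at or above `dx_age_min`).  Deaths from cancers diagnosed
#' before the first invitation to screening -- women who could not have
#' benefitted -- contribute nothing.  Deaths outside the grid's follow-up
#' window or the death-age window are excluded and counted in the exclusion
#' log.
#'
#' @param records a `registry_records` data frame.
#' @param spec a [lexis_spec()].
#' @param dx_year_min first diagnosis year admitted (default: first grid
#'   year).
#' @param dx_age_min youngest diagnosis age admitted (default 50).
#' @param death_age_range inclusive age window for the death itself
#'   (default `c(50, 84)`; the oldest grid age row then carries person-time
#'   only).
#' @return A [lexis_grid()] with the `deaths` layer filled (person-time
#'   unset) and an integer exclusion tally in attribute `"exclusions"`.
#' @export
tabulate_mortality <- function(records, spec,
                               dx_year_min = min(spec$years),
                               dx_age_min = 50L,
                               death_age_range = c(50L, 84L)) {
  stopifnot(inherits(spec, "lexis_spec"))
  r <- as.data.frame(records)
  bc <- !is.na(r$death_cause) & r$death_cause == "breast_cancer" &
    !is.na(r$death_year)
  r <- r[bc, , drop = FALSE]
  age_death <- r$age_dx + (r$death_year - r$year_dx)

  excl <- c(pre_window_diagnosis = 0L, young_diagnosis = 0L,
            death_outside_followup = 0L, death_age_outside_window = 0L,
            outside_grid = 0L, non_breast_cause = sum(!bc, na.rm = TRUE))
  take <- rep(TRUE, nrow(r))
  mark <- function(bad, key) {
    excl[key] <<- excl[key] + sum(bad & take)
    take <<- take & !bad
  }
  mark(r$year_dx < dx_year_min, "pre_window_diagnosis")
  mark(r$age_dx < dx_age_min, "young_diagnosis")
  mark(r$death_year < min(spec$years) | r$death_year > max(spec$years),
       "death_outside_followup")
  mark(age_death < death_age_range[1] | age_death > death_age_range[2],
       "death_age_outside_window")
  mark(!(age_death %in% spec$ages) | !(r$region %in% spec$regions),
       "outside_grid")

  kept <- r[take, , drop = FALSE]
  tab <- if (nrow(kept) > 0) {
    stats::aggregate(
      list(deaths = rep(1L, nrow(kept))),
      by = list(age = kept$age_dx + (kept$death_year - kept$year_dx),
                year = kept$death_year, region = kept$region),
      FUN = sum)
  } else NULL
  g <- lexis_grid(spec, deaths = tab)
  attr(g, "exclusions") <- excl
  g
}

#' Tabulate stage 2-4 diagnoses onto a Lexis grid
#'
#' A record adds one case to cell (age at diagnosis, year of diagnosis) of
#' its region when its stage class is `stage2_4` and the cell lies on the
#' grid.  Records with unknown stage are excluded (not imputed) and counted
#' in the exclusion log, as are stage 2-4 diagnoses falling off the grid.
#'
#' @param records a `registry_records` data frame.
#' @param spec a [lexis_spec()].
#' @return A [lexis_grid()] with the `stage24_cases` layer filled and an
#'   exclusion tally in attribute `"exclusions"`.
#' @export
tabulate_stage24 <- function(records, spec) {
  stopifnot(inherits(spec, "lexis_spec"))
  r <- as.data.frame(records)
  excl <- c(unknown_stage = sum(r$stage_class == "unknown"),
            outside_grid = 0L)
  r <- r[r$stage_class == "stage2_4", , drop = FALSE]
  in_grid <- r$age_dx %in% spec$ages & r$year_dx %in% spec$years &
    r$region %in% spec$regions
  excl["outside_grid"] <- sum(!in_grid)
  kept <- r[in_grid, , drop = FALSE]
  tab <- if (nrow(kept) > 0) {
    stats::aggregate(
      list(stage24_cases = rep(1L, nrow(kept))),
      by = list(age = kept$age_dx, year = kept$year_dx,
                region = kept$region),
      FUN = sum)
  } else NULL
  g <- lexis_grid(spec, stage24_cases = tab)
  attr(g, "exclusions") <- excl
  g
}

#' Assemble a full Lexis grid from records and a denominator table
#'
#' Convenience wrapper running [tabulate_mortality()] and
#' [tabulate_stage24()] and attaching the person-time table (person-time is
#' always supplied as a separate denominator table; it is never derived
#' from the records themselves).
#'
#' @param records a `registry_records` data frame.
#' @param women_years data frame with columns `age`, `year`, `region`,
#'   `women_years` covering every grid cell.
#' @param spec a [lexis_spec()].
#' @param ... passed to [tabulate_mortality()].
#' @return A validated [lexis_grid()] with all three layers filled.
#' @export
build_lexis_grid <- function(records, women_years, spec, ...) {
  gm <- tabulate_mortality(records, spec, ...)
  gs <- tabulate_stage24(records, spec)
  wy <- as.data.frame(women_years)
  full <- expand.grid(age = spec$ages, year = spec$years,
                      region = spec$regions, KEEP.OUT.ATTRS = FALSE)
  i <- match(cell_id(full$age, full$year, full$region),
             cell_id(wy$age, wy$year, wy$region))
  full$women_years <- ifelse(is.na(i), 0, wy$women_years[i])
  g <- lexis_grid(spec)
  g$deaths <- gm$deaths
  g$stage24_cases <- gs$stage24_cases
  g$women_years <- full$women_years
  attr(g, "exclusions") <- list(mortality = attr(gm, "exclusions"),
                                stage24 = attr(gs, "exclusions"))
  validate_lexis_grid(g)
  g
}
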