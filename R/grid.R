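# The LexisGrid container: per (age, year, region) event counts and
# person-time, in long format, with CSV serialization.

#' Construct a Lexis grid of counts and person-time
#'
#' The grid is stored long: one row per (age, year, region) with columns
#' `deaths`, `stage24_cases` and `women_years`.  Counts default to zero;
#' person-time defaults to `NA` until a denominator table is supplied
#' (serialized grids must have it filled in).
#'
#' @param spec a [lexis_spec()].
#' @param deaths,stage24_cases,women_years optional data frames with columns
#'   `age`, `year`, `region` and a value column (`deaths`, `stage24_cases`
#'   or `women_years`) used to fill the corresponding layer; cells not
#'   listed keep the default (0 for counts, `NA` for person-time).
#' @return An object of class `lexis_grid` (a data frame) with the spec
#'   attached as attribute `spec`.
#' @export
lexis_grid <- function(spec, deaths = NULL, stage24_cases = NULL,
                       women_years = NULL) {
  stopifnot(inherits(spec, "lexis_spec"))
  base <- expand.grid(age = spec$ages, year = spec$years,
                      region = spec$regions, KEEP.OUT.ATTRS = FALSE)
  base$deaths <- 0L
  base$stage24_cases <- 0L
  base$women_years <- NA_real_
  g <- structure(base, spec = spec, class = c("lexis_grid", "data.frame"))
  if (!is.null(deaths)) g <- fill_grid_layer(g, deaths, "deaths")
  if (!is.null(stage24_cases))
    g <- fill_grid_layer(g, stage24_cases, "stage24_cases")
  if (!is.null(women_years))
    g <- fill_grid_layer(g, women_years, "women_years")
  g
}

grid_spec <- function(grid) {
  sp <- attr(grid, "spec")
  if (is.null(sp)) stop("grid has no attached 'lexis_spec'")
  sp
}

cell_id <- function(age, year, region) paste(age, year, region, sep = "|")

fill_grid_layer <- function(grid, tab, col) {
  tab <- as.data.frame(tab)
  need <- c("age", "year", "region", col)
  if (!all(need %in% names(tab)))
    stop("layer table for '", col, "' needs columns: ",
         paste(need, collapse = ", "))
  i <- match(cell_id(tab$age, tab$year, tab$region),
             cell_id(grid$age, grid$year, grid$region))
  if (anyNA(i))
    stop(sum(is.na(i)), " rows of the '", col,
         "' table fall outside the grid")
  grid[[col]][i] <- tab[[col]]
  grid
}

#' Validate a Lexis grid
#'
#' Checks structural invariants: counts are non-negative integers,
#' person-time is non-negative (or entirely unset), and a cell with zero
#' person-time carries no events.
#'
#' @param grid a [lexis_grid()].
#' @return The grid, invisibly; errors describe the first violation found.
#' @export
validate_lexis_grid <- function(grid) {
  stopifnot(inherits(grid, "lexis_grid"))
  for (col in c("deaths", "stage24_cases")) {
    v <- grid[[col]]
    if (anyNA(v) || any(v < 0) || any(v != round(v)))
      stop("'", col, "' must be non-negative integer counts")
  }
  wy <- grid$women_years
  has_wy <- !is.na(wy)
  if (any(has_wy) && !all(has_wy))
    stop("'women_years' must be set for every cell or for none")
  if (any(has_wy)) {
    if (any(wy < 0)) stop("'women_years' must be non-negative")
    empty <- wy == 0
    if (any(grid$deaths[empty] > 0 | grid$stage24_cases[empty] > 0))
      stop("cells with zero person-time must have zero event counts")
  }
  invisible(grid)
}

#' @export
print.lexis_grid <- function(x, ...) {
  sp <- grid_spec(x)
  cat("Lexis grid: ", length(sp$ages), " ages x ", length(sp$years),
      " years x ", length(sp$regions), " regions\n", sep = "")
  cat("  deaths:        ", sum(x$deaths), "\n", sep = "")
  cat("  stage 2-4:     ", sum(x$stage24_cases), "\n", sep = "")
  if (all(is.na(x$women_years))) {
    cat("  women-years:   (not set)\n")
  } else {
    cat("  women-years:   ", format(sum(x$women_years), big.mark = ","),
        "\n", sep = "")
  }
  invisible(x)
}

#' Extract one layer of a Lexis grid as an age-by-year matrix
#'
#' @param grid a [lexis_grid()].
#' @param what one of `"deaths"`, `"stage24_cases"`, `"women_years"`.
#' @param region region identifier.
#' @return Numeric matrix with ages in rows and years in columns, suitable
#'   for [smooth_3x3()].
#' @export
grid_matrix <- function(grid, what = c("deaths", "stage24_cases",
                                       "women_years"),
                        region) {
  what <- match.arg(what)
  sp <- grid_spec(grid)
  if (!region %in% sp$regions) stop("unknown region: ", region)
  sub <- grid[grid$region == region, ]
  m <- matrix(NA_real_, length(sp$ages), length(sp$years),
              dimnames = list(age = sp$ages, year = sp$years))
  m[cbind(match(sub$age, sp$ages), match(sub$year, sp$years))] <-
    as.numeric(sub[[what]])
  m
}

#' Write a Lexis grid to delimited text
#'
#' Long format, comma-separated, with header
#' `age,year,region,deaths,stage24_cases,women_years`.  Person-time must be
#' filled in before serialization.
#'
#' @param grid a [lexis_grid()].
#' @param path output file path.
#' @export
write_lexis_grid <- function(grid, path) {
  validate_lexis_grid(grid)
  if (anyNA(grid$women_years))
    stop("cannot serialize a grid with missing person-time")
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a Lexis grid from delimited text
#'
#' @param path file written by [write_lexis_grid()] (or matching its layout).
#' @return A validated [lexis_grid()].
#' @export
read_lexis_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("age", "year", "region", "deaths", "stage24_cases",
            "women_years")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("grid file is missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(df$women_years))
    stop("grid file has missing person-time")
  spec <- lexis_spec(ages = sort(unique(df$age)),
                     years = sort(unique(df$year)),
                     regions = unique(df$region))
  g <- lexis_grid(spec,
                  deaths = df[need[1:4]],
                  stage24_cases = df[c(need[1:3], "stage24_cases")],
                  women_years = df[c(need[1:3], "women_years")])
  validate_lexis_grid(g)
  g
}
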