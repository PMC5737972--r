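# shared fixtures, all built in code

# person-time table shaped like the study: ~2.90/2.67 million women-years in
# the eligible polygon, ~0.91/0.90 million in the too-old polygon
study_women_years <- function(spec, part) {
  wy <- expand.grid(age = spec$ages, year = spec$years,
                    region = spec$regions, KEEP.OUT.ATTRS = FALSE)
  lab <- part$label[match(paste(wy$age, wy$year),
                          paste(part$age, part$year))]
  idx <- wy$region == spec$regions[1]
  wy$women_years <- ifelse(lab == "eligible",
                           ifelse(idx, 2.90e6 / 301, 2.67e6 / 301),
                           ifelse(idx, 0.91e6 / 203, 0.90e6 / 203))
  wy
}

# cohort-based death rate: eligible-cohort cells at the study's eligible
# death rate, too-old cohorts at the (higher) old-age rate
study_death_rate <- function(age, year) {
  ifelse(age - (year - 2000) >= 65, 727 / 0.90e6, 1095 / 2.67e6)
}

# quick registry-record data frame with sensible defaults
make_records <- function(region = 1L, year_dx = 2003L, age_dx = 60L,
                         stage_class = "stage2_4", death_year = NA,
                         death_cause = NA) {
  data.frame(region = region, year_dx = year_dx, age_dx = age_dx,
             stage_class = stage_class, death_year = death_year,
             death_cause = death_cause, stringsAsFactors = FALSE)
}

write_tmp_registry <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  path
}

# brute-force truncated-window 3x3 mean, kept deliberately naive as an
# independent oracle for smooth_3x3
naive_window_mean <- function(x) {
  out <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(x) && jj >= 1 && jj <= ncol(x))
        vals <- c(vals, x[ii, jj])
    }
    out[i, j] <- mean(vals)
  }
  out
}
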