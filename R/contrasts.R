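# Between-region contrasts: stratified Mantel-Haenszel rate ratios with the
# Breslow-Day person-time variance, the Woolf-like variance approximation,
# and the double-difference (ratio of rate ratios) net-effect estimator.

Z95 <- 1.96  # fixed normal quantile: all intervals are 95%

#' Mantel-Haenszel summary rate ratio over person-time strata
#'
#' For strata i with event counts `d1_i`, `d0_i` and person-time `t1_i`,
#' `t0_i` in the index and reference arms, the summary ratio is
#' \deqn{RR = \frac{\sum_i d_{1i} t_{0i} / t_i}{\sum_i d_{0i} t_{1i} / t_i},
#'   \quad t_i = t_{1i} + t_{0i}.}
#' The variance of its logarithm uses the Breslow-Day person-time formula,
#' \eqn{\sum_i d_i t_{1i} t_{0i} / t_i^2} divided by the product of the two
#' MH sums (with \eqn{d_i = d_{1i} + d_{0i}}); when person-time is nearly
#' balanced this is well approximated by `1/D1 + 1/D0`, the reciprocal total
#' death counts, which is also reported.
#'
#' Strata with no person-time at all are skipped silently (but counted);
#' strata that carry events but have person-time on one side only are
#' dropped with a warning.
#'
#' @param d1,t1 events and person-time in the index arm, one value per
#'   stratum.
#' @param d0,t0 events and person-time in the reference arm.
#' @return An object of class `rate_ratio` with fields `estimate`,
#'   `log_variance`, `log_variance_approx`, `ci95`, `D1`, `D0`, `n_strata`,
#'   `n_dropped`.
#' @examples
#' # a single stratum reduces to the crude rate ratio
#' mh_rate_ratio(2, 1, 1, 1)$estimate  # 2
#' @export
mh_rate_ratio <- function(d1, t1, d0, t0) {
  k <- length(d1)
  if (length(t1) != k || length(d0) != k || length(t0) != k)
    stop("stratum vectors must have equal length")
  if (any(c(d1, d0) < 0) || any(c(d1, d0) != round(c(d1, d0))))
    stop("event counts must be non-negative integers")
  if (any(c(t1, t0) < 0)) stop("person-time must be non-negative")
  tot <- t1 + t0
  empty <- tot == 0
  onesided <- !empty & (d1 + d0 > 0) & (t1 == 0 | t0 == 0)
  if (any(onesided))
    warning(sum(onesided),
            " strata with events but one-sided person-time dropped")
  keep <- !empty & !onesided
  if (!any(keep)) stop("no usable strata")
  d1 <- d1[keep]; t1 <- t1[keep]; d0 <- d0[keep]; t0 <- t0[keep]
  tot <- tot[keep]
  if (sum(d1 + d0) == 0) stop("no events in any stratum")
  num <- sum(d1 * t0 / tot)
  den <- sum(d0 * t1 / tot)
  if (den == 0)
    stop("Mantel-Haenszel ratio undefined: no weighted events in the ",
         "reference arm")
  est <- num / den
  D1 <- sum(d1)
  D0 <- sum(d0)
  if (num > 0) {
    logv <- sum((d1 + d0) * t1 * t0 / tot^2) / (num * den)
    ci <- ratio_ci(est, logv)
  } else {
    logv <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(estimate = est,
                 log_variance = logv,
                 log_variance_approx =
                   if (D1 > 0 && D0 > 0) 1 / D1 + 1 / D0 else NA_real_,
                 ci95 = ci,
                 D1 = D1, D0 = D0,
                 n_strata = sum(keep),
                 n_dropped = sum(!keep)),
            class = "rate_ratio")
}

#' @export
print.rate_ratio <- function(x, ...) {
  cat("Mantel-Haenszel rate ratio: ", sprintf("%.2f", x$estimate),
      "  (95% CI ", sprintf("%.2f", x$ci95[1]), " to ",
      sprintf("%.2f", x$ci95[2]), ")\n", sep = "")
  cat("  deaths/events: D1 = ", x$D1, ", D0 = ", x$D0,
      "; strata used: ", x$n_strata, "\n", sep = "")
  invisible(x)
}

#' 95% interval for a ratio from the variance of its logarithm
#'
#' @param estimate positive ratio estimate.
#' @param log_variance variance of `log(estimate)`.
#' @return `c(lower, upper)` on the ratio scale,
#'   `estimate * exp(±1.96 sqrt(log_variance))`.
#' @export
ratio_ci <- function(estimate, log_variance) {
  estimate * exp(c(-1, 1) * Z95 * sqrt(log_variance))
}

#' Woolf-like variance of a log ratio of rate ratios
#'
#' The log-scale variance of a double difference built from two
#' between-region contrasts is well approximated by the sum of reciprocal
#' total event counts, `1/D1 + 1/D0 + 1/D1p + 1/D0p`, so the width of the
#' resulting confidence interval is governed by the smallest of the four
#' counts.
#'
#' @param D1,D0 total events in the two arms of the first contrast.
#' @param D1p,D0p total events in the two arms of the second contrast.
#' @return The approximate variance (positive scalar).
#' @examples
#' woolf_variance(1027, 1095, 702, 727)
#' @export
woolf_variance <- function(D1, D0, D1p, D0p) {
  counts <- c(D1, D0, D1p, D0p)
  if (any(counts <= 0))
    stop("all four event counts must be positive for the Woolf-like ",
         "approximation")
  sum(1 / counts)
}

#' Double-difference net effect of earlier screening
#'
#' Divides the eligible-cohort rate ratio by the background (too-old) rate
#' ratio, removing inherent between-region differences; the remainder is
#' attributable to the earlier programme start in the index region.  The
#' log variance is the sum of the two component log variances.  The percent
#' reduction is also converted into an absolute number of deaths averted
#' (scaled by the reference-arm eligible deaths) and deattenuated by the
#' participation fraction into a full-participation efficacy estimate.
#'
#' @param rr_eligible `rate_ratio` for the screening-eligible cells.
#' @param rr_background `rate_ratio` for the too-old cells.
#' @param participation fraction of invitees attending screening, in
#'   `(0, 1]` (default 0.70).
#' @return An object of class `double_difference` with fields `net_ratio`,
#'   `log_variance`, `ci95` (ratio scale), `percent_reduction`,
#'   `percent_reduction_ci` (ascending, negative values are increases),
#'   `deaths_averted`, `efficacy_estimate`, `woolf_variance` and the four
#'   death totals.
#' @export
double_difference <- function(rr_eligible, rr_background,
                              participation = 0.70) {
  stopifnot(inherits(rr_eligible, "rate_ratio"),
            inherits(rr_background, "rate_ratio"))
  if (!is.numeric(participation) || participation <= 0 || participation > 1)
    stop("'participation' must lie in (0, 1]")
  if (rr_background$estimate == 0)
    stop("background rate ratio is zero; net ratio undefined")
  net <- rr_eligible$estimate / rr_background$estimate
  logv <- rr_eligible$log_variance + rr_background$log_variance
  ci <- ratio_ci(net, logv)
  pct <- 100 * (1 - net)
  woolf <- if (all(c(rr_eligible$D1, rr_eligible$D0,
                     rr_background$D1, rr_background$D0) > 0))
    woolf_variance(rr_eligible$D1, rr_eligible$D0,
                   rr_background$D1, rr_background$D0)
  else NA_real_
  structure(list(net_ratio = net,
                 log_variance = logv,
                 ci95 = ci,
                 percent_reduction = pct,
                 percent_reduction_ci = 100 * (1 - rev(ci)),
                 deaths_averted = (1 - net) * rr_eligible$D0,
                 efficacy_estimate = pct / participation,
                 participation = participation,
                 woolf_variance = woolf,
                 D1 = rr_eligible$D1, D0 = rr_eligible$D0,
                 D1p = rr_background$D1, D0p = rr_background$D0),
            class = "double_difference")
}

#' @export
print.double_difference <- function(x, ...) {
  cat("Double difference (net effect of earlier screening)\n")
  cat("  net rate ratio:    ", sprintf("%.2f", x$net_ratio),
      "  (95% CI ", sprintf("%.2f", x$ci95[1]), " to ",
      sprintf("%.2f", x$ci95[2]), ")\n", sep = "")
  cat("  percent reduction: ", sprintf("%.0f%%", x$percent_reduction),
      "  (95% CI ", sprintf("%.0f%%", x$percent_reduction_ci[1]), " to ",
      sprintf("%.0f%%", x$percent_reduction_ci[2]), ")\n", sep = "")
  cat("  deaths averted:    ", sprintf("%.0f", x$deaths_averted),
      "\n", sep = "")
  cat("  efficacy at full participation (", 100 * x$participation,
      "% uptake): ", sprintf("%.0f%%", x$efficacy_estimate), "\n", sep = "")
  invisible(x)
}

#' Between-region MH contrast on one eligibility polygon of a grid
#'
#' Builds one stratum per Lexis cell carrying the chosen polygon's label
#' (the age-and-year matching) and summarises the first-region versus
#' second-region event rates with [mh_rate_ratio()].
#'
#' @param grid a [lexis_grid()] with person-time filled in.
#' @param partition an [partition_cells()] result on the same spec.
#' @param subset `"eligible"` or `"too_old"`.
#' @param events `"deaths"` or `"stage24_cases"`.
#' @return A `rate_ratio` object.
#' @export
region_contrast <- function(grid, partition,
                            subset = c("eligible", "too_old"),
                            events = c("deaths", "stage24_cases")) {
  subset <- match.arg(subset)
  events <- match.arg(events)
  sp <- grid_spec(grid)
  strata <- contrast_strata(grid, partition, subset, events)
  mh_rate_ratio(strata$d1, strata$t1, strata$d0, strata$t0)
}

# per-cell (d1, t1, d0, t0) strata for the cells of one polygon
contrast_strata <- function(grid, partition, subset, events) {
  sp <- grid_spec(grid)
  want <- partition[partition$label == subset, c("age", "year")]
  g1 <- grid[grid$region == sp$regions[1], ]
  g0 <- grid[grid$region == sp$regions[2], ]
  i1 <- match(cell_id(want$age, want$year, sp$regions[1]),
              cell_id(g1$age, g1$year, g1$region))
  i0 <- match(cell_id(want$age, want$year, sp$regions[2]),
              cell_id(g0$age, g0$year, g0$region))
  if (anyNA(i1) || anyNA(i0))
    stop("partition refers to cells outside the grid")
  data.frame(age = want$age, year = want$year,
             d1 = g1[[events]][i1], t1 = g1$women_years[i1],
             d0 = g0[[events]][i0], t0 = g0$women_years[i0])
}
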