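# Conditional-Poisson model of the time-varying net stage 2-4 deficit.
#
# Conditioning on the total number of events in each (age, year) Lexis cell
# turns the region-1 count into a binomial variable whose success logit is
# the log person-time ratio (offset) plus the log background rate ratio
# (offset, estimated from the too-old cells) plus the log net rate ratio,
# which may be constant, linear or quadratic in (centred) calendar year.
# One minus the fitted net ratio in year y is the fraction of the initial
# stage 2-4 "target" already removed, in that year, by earlier screening.

# stable log(1 + exp(eta))
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

# binomial-split log-likelihood maximiser (quasi-Newton on the analytic
# log-likelihood and gradient; convergence on relative log-likelihood
# change, see 'reltol')
fit_binom_split <- function(n1, n, off, X, start = NULL,
                            reltol = 1e-12, maxit = 500L) {
  nll <- function(beta) {
    eta <- off + drop(X %*% beta)
    -sum(n1 * eta - n * log1pexp(eta))
  }
  grad <- function(beta) {
    eta <- off + drop(X %*% beta)
    -drop(crossprod(X, n1 - n * stats::plogis(eta)))
  }
  start <- start %||% rep(0, ncol(X))
  opt <- stats::optim(start, nll, grad, method = "BFGS", hessian = TRUE,
                      control = list(reltol = reltol, maxit = maxit))
  if (opt$convergence != 0)
    stop("binomial-split fit did not converge (optim code ",
         opt$convergence, "): ", opt$message %||% "",
         "; function evaluations: ", opt$counts[["function"]],
         ", gradient evaluations: ", opt$counts[["gradient"]])
  vcov <- tryCatch(solve(opt$hessian), error = function(e) {
    warning("information matrix is singular; standard errors unavailable")
    matrix(NA_real_, ncol(X), ncol(X))
  })
  loglik <- -opt$value + sum(lchoose(n, n1))
  list(coefficients = stats::setNames(opt$par, colnames(X)),
       vcov = structure(vcov, dimnames = list(colnames(X), colnames(X))),
       loglik = loglik,
       loglik_null = -nll(rep(0, ncol(X))) + sum(lchoose(n, n1)),
       counts = opt$counts, convergence = opt$convergence)
}

#' Background log rate ratio from the too-old cells
#'
#' Constant-only binomial-split fit over the cells whose cohorts were too
#' old to be invited: the estimate captures inherent between-region
#' differences in incidence unrelated to screening, and is plugged into
#' [netfit()] as a fixed offset.
#'
#' @param grid a [lexis_grid()] with person-time.
#' @param partition an eligibility partition on the same spec.
#' @param events grid layer to model (default `"stage24_cases"`).
#' @return List with `estimate` (log rate ratio), `se`, `n_cells`,
#'   `loglik`.
#' @export
background_log_rr <- function(grid, partition, events = "stage24_cases") {
  s <- contrast_strata(grid, partition, "too_old", events)
  s <- s[s$d1 + s$d0 > 0, ]
  if (nrow(s) == 0) stop("no events in the too-old cells")
  if (any(s$t1 <= 0 | s$t0 <= 0))
    stop("cells with events need positive person-time in both regions")
  fit <- fit_binom_split(s$d1, s$d1 + s$d0, log(s$t1 / s$t0),
                         matrix(1, nrow(s), 1,
                                dimnames = list(NULL, "(Intercept)")))
  list(estimate = unname(fit$coefficients), se = sqrt(fit$vcov[1, 1]),
       n_cells = nrow(s), loglik = fit$loglik)
}

#' Fit the time-varying net stage 2-4 deficit model
#'
#' Conditional-Poisson regression over the screening-eligible Lexis cells:
#' fixing each cell's total event count `n`, the index-region count is
#' binomial with
#' \deqn{\mathrm{logit}\, p_{ay} = \log(T_{1,ay}/T_{0,ay}) + \beta_{bg}
#'   + \log \mathrm{netRR}(y),}
#' where `log netRR(y) = b0 + b1 yc + b2 yc^2` on calendar year centred at
#' the study midpoint.  The background term is estimated first from the
#' too-old cells (constant model) and entered as a fixed offset, not
#' re-estimated.  `1 - netRR(y)` is the fraction of the stage 2-4 cancers
#' that would have surfaced in year y already removed by earlier screening.
#'
#' @param grid a [lexis_grid()] with person-time filled in.
#' @param partition an eligibility partition on the same spec.
#' @param basis time basis for the log net ratio: `"constant"`, `"linear"`
#'   or `"quadratic"` (default).
#' @param background optional known background log rate ratio; when `NULL`
#'   it is estimated via [background_log_rr()].
#' @param events grid layer to model (default `"stage24_cases"`).
#' @param reltol relative log-likelihood convergence tolerance of the
#'   quasi-Newton maximiser.
#' @return An object of class `netfit`, with `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `fitted`, `residuals`, `simulate` and `plot`
#'   methods; see [predict.netfit()] and [plot.netfit()].
#' @examples
#' sp <- lexis_spec(50:54, 2000:2004)
#' part <- partition_cells(sp, cutoff = 64)
#' wy <- expand.grid(age = sp$ages, year = sp$years, region = sp$regions)
#' wy$women_years <- 1000
#' set.seed(1)
#' cases <- wy
#' names(cases)[4] <- "stage24_cases"
#' cases$stage24_cases <- rpois(nrow(cases), 5)
#' g <- lexis_grid(sp, stage24_cases = cases, women_years = wy)
#' fit <- netfit(g, part, basis = "constant", background = 0)
#' coef(fit)
#' @export
netfit <- function(grid, partition,
                   basis = c("quadratic", "linear", "constant"),
                   background = NULL, events = "stage24_cases",
                   reltol = 1e-12) {
  basis <- match.arg(basis)
  sp <- grid_spec(grid)
  bg_fit <- NULL
  if (is.null(background)) {
    bg_fit <- background_log_rr(grid, partition, events)
    background <- bg_fit$estimate
  }
  s <- contrast_strata(grid, partition, "eligible", events)
  s <- s[s$d1 + s$d0 > 0, ]
  if (nrow(s) == 0) stop("no events in the eligible cells")
  if (any(s$t1 <= 0 | s$t0 <= 0))
    stop("cells with events need positive person-time in both regions")
  if (sum(s$d1) == 0 || sum(s$d0) == 0)
    stop("separation: all eligible-cell events fall in one region")
  center <- mean(range(sp$years))
  X <- time_basis(s$year, center, basis)
  fit <- fit_binom_split(s$d1, s$d1 + s$d0,
                         log(s$t1 / s$t0) + background, X,
                         reltol = reltol)
  Xy <- time_basis(sp$years, center, basis)
  net <- drop(exp(Xy %*% fit$coefficients))
  structure(list(coefficients = fit$coefficients,
                 vcov = fit$vcov,
                 background_log_rr = background,
                 background_fit = bg_fit,
                 basis = basis,
                 year_center = center,
                 years = sp$years,
                 net_ratio = stats::setNames(net, sp$years),
                 deficit = stats::setNames(1 - net, sp$years),
                 loglik = fit$loglik,
                 loglik_null = fit$loglik_null,
                 convergence = fit$convergence,
                 counts = fit$counts,
                 data = s,
                 events = events,
                 spec = sp),
            class = "netfit")
}

time_basis <- function(year, center, basis) {
  yc <- year - center
  X <- switch(basis,
              constant = cbind("(Intercept)" = rep(1, length(yc))),
              linear = cbind("(Intercept)" = 1, year_c = yc),
              quadratic = cbind("(Intercept)" = 1, year_c = yc,
                                year_c2 = yc^2))
  X
}

#' @export
print.netfit <- function(x, ...) {
  cat("Net stage 2-4 deficit model (conditional Poisson, ", x$basis,
      "-in-time)\n", sep = "")
  cat("  background log rate ratio (offset): ",
      sprintf("%.4f", x$background_log_rr), "\n", sep = "")
  cat("  coefficients (year centred at ", x$year_center, "):\n", sep = "")
  print(round(x$coefficients, 5))
  rng <- range(x$deficit)
  cat("  fitted net deficit 1 - netRR(y): ",
      sprintf("%.1f%%", 100 * rng[1]), " to ",
      sprintf("%.1f%%", 100 * rng[2]), " across ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  invisible(x)
}

#' @export
summary.netfit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab,
                 background_log_rr = object$background_log_rr,
                 background_fit = object$background_fit,
                 basis = object$basis,
                 loglik = object$loglik,
                 loglik_null = object$loglik_null,
                 n_cells = nrow(object$data),
                 deficit = object$deficit),
            class = "summary.netfit")
}

#' @export
print.summary.netfit <- function(x, ...) {
  cat("Conditional-Poisson net deficit model (", x$basis,
      "-in-time) on ", x$n_cells, " event-bearing cells\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nBackground log rate ratio (fixed offset): ",
      sprintf("%.4f", x$background_log_rr), sep = "")
  if (!is.null(x$background_fit))
    cat("  (SE ", sprintf("%.4f", x$background_fit$se), ", from ",
        x$background_fit$n_cells, " too-old cells)", sep = "")
  cat("\nLog-likelihood: ", sprintf("%.2f", x$loglik),
      " (null, netRR = 1: ", sprintf("%.2f", x$loglik_null), ")\n",
      sep = "")
  invisible(x)
}

#' @export
coef.netfit <- function(object, ...) object$coefficients

#' @export
vcov.netfit <- function(object, ...) object$vcov

#' @export
logLik.netfit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = nrow(object$data), class = "logLik")
}

#' Predicted net rate ratio or deficit by calendar year
#'
#' @param object a [netfit()] model.
#' @param years calendar years to evaluate (default: the study years).
#' @param type `"net_ratio"` for netRR(y), `"deficit"` for 1 - netRR(y),
#'   `"link"` for log netRR(y).
#' @param ... unused.
#' @return Named numeric vector over `years`.
#' @export
predict.netfit <- function(object, years = object$years,
                           type = c("net_ratio", "deficit", "link"), ...) {
  type <- match.arg(type)
  eta <- drop(time_basis(years, object$year_center, object$basis) %*%
                object$coefficients)
  out <- switch(type, net_ratio = exp(eta), deficit = 1 - exp(eta),
                link = eta)
  stats::setNames(out, years)
}

#' @export
fitted.netfit <- function(object, ...) {
  s <- object$data
  eta <- log(s$t1 / s$t0) + object$background_log_rr +
    drop(time_basis(s$year, object$year_center, object$basis) %*%
           object$coefficients)
  stats::plogis(eta)
}

#' @export
residuals.netfit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  s <- object$data
  n <- s$d1 + s$d0
  p <- fitted(object)
  if (type == "pearson") {
    (s$d1 - n * p) / sqrt(n * p * (1 - p))
  } else {
    d1 <- s$d1
    ll <- ifelse(d1 > 0, d1 * log(d1 / (n * p)), 0) +
      ifelse(n - d1 > 0, (n - d1) * log((n - d1) / (n * (1 - p))), 0)
    sign(d1 - n * p) * sqrt(2 * ll)
  }
}

#' Simulate index-region splits from a fitted net deficit model
#'
#' Draws the region-1 count of each event-bearing cell from its fitted
#' binomial distribution (totals stay fixed, as in the conditioning).
#'
#' @param object a [netfit()] model.
#' @param nsim number of replicate draws.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return Data frame with the cell identifiers and one `sim_*` column of
#'   region-1 counts per replicate.
#' @export
simulate.netfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$data
  n <- s$d1 + s$d0
  p <- fitted(object)
  sims <- replicate(nsim, stats::rbinom(length(n), n, p))
  colnames(sims) <- paste0("sim_", seq_len(nsim))
  cbind(s[c("age", "year")], as.data.frame(sims))
}

#' Plot the fitted net deficit with optional yearly MH points
#'
#' Displays the year-specific percent difference between the regions,
#' `100 * (netRR(y) - 1)`, as a smooth curve, optionally overlaying the
#' age-matched yearly Mantel-Haenszel ratios from [yearly_mh_ratios()].
#'
#' @param x a [netfit()] model.
#' @param yearly optional data frame from [yearly_mh_ratios()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.netfit <- function(x, yearly = NULL, ...) {
  yy <- seq(min(x$years), max(x$years), by = 0.1)
  smooth <- 100 * (predict(x, yy) - 1)
  ylim <- range(smooth, if (!is.null(yearly))
    100 * (c(yearly$estimate, yearly$lcl, yearly$ucl) - 1), na.rm = TRUE)
  graphics::plot(yy, smooth, type = "l", lwd = 2, ylim = ylim,
                 xlab = "Year", ylab = "Region difference (%)", ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(yearly)) {
    graphics::points(yearly$year, 100 * (yearly$estimate - 1), pch = 16)
    graphics::segments(yearly$year, 100 * (yearly$lcl - 1),
                       yearly$year, 100 * (yearly$ucl - 1))
  }
  invisible(x)
}
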