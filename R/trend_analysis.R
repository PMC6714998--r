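#' @title Linear trends in annual cost totals
#' @description Ordinary least-squares fits of annual totals against fiscal
#'   year, with a two-sided t-test of the slope, for the whole population
#'   and for each pyramid segment.
#' @name trend_analysis
NULL

#' Fit a linear trend of annual totals against fiscal year
#'
#' OLS of `totals ~ years` with the fiscal-year label as a numeric
#' regressor. The slope is the expected annual cost change; its two-sided
#' t-test uses n - 2 degrees of freedom. Recoding year labels (e.g.
#' 2011..2015 to 0..4) changes the intercept only.
#'
#' Degenerate fits with zero residual variance are given a defined answer
#' rather than NaN: an exact flat line has `p_value = 1` (no evidence of a
#' trend), an exact sloped line `p_value = 0`; `t_stat` is `NA` in both.
#'
#' @param years Strictly increasing numeric year labels, length >= 3.
#' @param totals Annual totals, same length (any fixed unit; slope is in
#'   that unit per year).
#' @return Object of class `trend_fit`: list with `n_years`, `slope`,
#'   `intercept`, `slope_se`, `t_stat`, `p_value`, `r_squared`.
#' @export
fit_linear_trend <- function(years, totals) {
  years <- as.numeric(years); totals <- as.numeric(totals)
  if (length(years) != length(totals)) stop("years and totals lengths differ")
  if (length(years) < 3L) stop("need at least 3 annual points")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")

  fit <- stats::lm(totals ~ years)
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  slope <- unname(stats::coef(fit)[["years"]])
  se <- unname(co["years", "Std. Error"])
  scale <- mean(abs(totals)) + .Machine$double.xmin
  zero_slope <- abs(slope) * diff(range(years)) < 1e-10 * scale
  if (!is.finite(se) || sm$sigma < 1e-10 * scale) {
    # exact line (zero residual variance): no sampling variability to test
    t_stat <- NA_real_
    p <- if (zero_slope) 1 else 0
    se <- 0
    r2 <- if (zero_slope) 0 else 1
  } else {
    t_stat <- unname(co["years", "t value"])
    p <- unname(co["years", "Pr(>|t|)"])
    r2 <- sm$r.squared
  }
  structure(list(
    n_years = length(years),
    slope = slope,
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    slope_se = se,
    t_stat = t_stat,
    p_value = p,
    r_squared = r2
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.4g per year (SE %.3g), p = %s, R^2 = %.3f, n = %d\n",
              x$slope, x$slope_se, format_p(x$p_value), x$r_squared, x$n_years))
  invisible(x)
}

#' Annual trend fits for the population and each segment
#'
#' Fits four OLS trends — population total and the T, M, B segment totals
#' by fiscal year — on totals expressed in millions of dollars. Because
#' segment totals sum to the population total each year and all four fits
#' share the same regressor, the population slope equals the sum of the
#' three segment slopes exactly.
#'
#' @param pyramids List of `cost_pyramid` objects for at least 3 distinct
#'   fiscal years.
#' @return Named list (`population`, `T`, `M`, `B`) of [fit_linear_trend]
#'   results; slopes are in US $M per year.
#' @export
segment_trends <- function(pyramids) {
  if (!all(vapply(pyramids, inherits, TRUE, "cost_pyramid"))) {
    stop("pyramids must be a list of cost_pyramid objects")
  }
  years <- vapply(pyramids, function(p) p$fiscal_year, 0L)
  if (anyDuplicated(years)) stop("duplicate fiscal years among pyramids")
  ord <- order(years)
  years <- years[ord]; pyramids <- pyramids[ord]
  if (length(years) < 3L) stop("need pyramids for at least 3 years")

  totals_m <- function(extract) {
    vapply(pyramids, extract, 0) / 1e6
  }
  fits <- list(population = fit_linear_trend(years, totals_m(function(p) p$total_cost)))
  for (s in SEGMENTS) {
    fits[[s]] <- fit_linear_trend(
      years, totals_m(function(p) p$segment_totals[[s]]))
  }
  fits
}
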