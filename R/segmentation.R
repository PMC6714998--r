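#' @title Cost acuity pyramid segmentation
#' @description Rank one fiscal year's utilizers by annual cost and split
#'   them into the top 5% (T), middle 45% (M) and bottom 50% (B) segments.
#' @name segmentation
NULL

# Segment labels, ordered high to low; "up" always means toward T.
SEGMENTS <- c("T", "M", "B")

# numeric rank of a segment label: T = 3, M = 2, B = 1
segment_rank <- function(labels) {
  match(labels, rev(SEGMENTS))
}

#' Segment sizes for a population of n ranked patients
#'
#' Cumulative-floor rule: the T segment takes the `floor(0.05 n)` most
#' expensive patients, T and M together the top `floor(0.50 n)`, B the
#' rest. This is the convention that gives 110/993/1103 for n = 2206.
#'
#' @param n Number of patients with any cost in the year (>= 0).
#' @return Named integer vector `c(T = , M = , B = )`, summing to `n`.
#' @examples
#' segment_cutoffs(2206)  # 110 993 1103
#' @export
segment_cutoffs <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L) stop("n must be a single non-negative count")
  n_t <- as.integer(floor(0.05 * n))
  n_top_half <- as.integer(floor(0.50 * n))
  c(T = n_t, M = n_top_half - n_t, B = n - n_top_half)
}

#' Build the cost acuity pyramid for one fiscal year
#'
#' Patients with any utilization that year (a positive component cost) are
#' ranked by annual total cost, highest first, ties broken by ascending
#' `patient_id` so that membership is independent of input row order. The
#' first `floor(0.05 n)` form the T segment, the next patients up to
#' `floor(0.50 n)` the M segment, and the remainder the B segment.
#'
#' @param panel A [cost_panel].
#' @param fiscal_year Year label present in the panel.
#' @return An object of class `cost_pyramid`: a list with `fiscal_year`,
#'   `n`, `membership` (data.frame `patient_id`, `cost`, `segment` in rank
#'   order), `segment_sizes`, `thresholds` (minimum observed cost within T
#'   and within M), `segment_totals`, `segment_means`, `segment_sds`
#'   (sample SD), `segment_shares` and `total_cost`.
#' @export
build_pyramid <- function(panel, fiscal_year) {
  stopifnot(inherits(panel, "cost_panel"))
  yrs <- panel_years(panel)
  if (!(fiscal_year %in% yrs)) {
    stop("fiscal year ", fiscal_year, " not in panel (available: ",
         paste(yrs, collapse = ", "), ")")
  }
  sub <- panel[panel$fiscal_year == fiscal_year & has_utilization(panel), ,
               drop = FALSE]
  if (nrow(sub) == 0L) stop("no utilizers in fiscal year ", fiscal_year)

  ord <- order(-sub$total_cost, sub$patient_id)
  cost <- sub$total_cost[ord]
  ids <- sub$patient_id[ord]
  n <- length(ids)
  sizes <- segment_cutoffs(n)
  segment <- factor(rep(SEGMENTS, times = sizes), levels = SEGMENTS)

  totals <- vapply(SEGMENTS, function(s) round(sum(cost[segment == s]), 2), 0)
  means <- vapply(SEGMENTS, function(s) {
    if (sizes[[s]] == 0L) NA_real_ else mean(cost[segment == s])
  }, 0)
  sds <- vapply(SEGMENTS, function(s) {
    if (sizes[[s]] < 2L) NA_real_ else stats::sd(cost[segment == s])
  }, 0)
  total <- round(sum(totals), 2)
  shares <- if (total > 0) totals / total else totals * NA_real_

  structure(list(
    fiscal_year = as.integer(fiscal_year),
    n = n,
    membership = data.frame(patient_id = ids, cost = cost, segment = segment,
                            stringsAsFactors = FALSE),
    segment_sizes = sizes,
    thresholds = c(T = if (sizes[["T"]] > 0) min(cost[segment == "T"]) else NA_real_,
                   M = if (sizes[["M"]] > 0) min(cost[segment == "M"]) else NA_real_),
    segment_totals = totals,
    segment_means = means,
    segment_sds = sds,
    segment_shares = shares,
    total_cost = total
  ), class = "cost_pyramid")
}

#' Share of a year's total cost held by one segment
#'
#' @param pyramid A `cost_pyramid`.
#' @param segment One of `"T"`, `"M"`, `"B"`.
#' @return Fraction of the year's total cost (not rounded; round to integer
#'   percent only at report time).
#' @export
pyramid_share <- function(pyramid, segment) {
  stopifnot(inherits(pyramid, "cost_pyramid"))
  segment <- match.arg(segment, SEGMENTS)
  if (pyramid$total_cost <= 0) stop("pyramid has zero total cost")
  unname(pyramid$segment_totals[[segment]] / pyramid$total_cost)
}

# membership as a named character vector patient_id -> segment
membership_vector <- function(pyramid) {
  stats::setNames(as.character(pyramid$membership$segment),
                  pyramid$membership$patient_id)
}

#' @export
print.cost_pyramid <- function(x, ...) {
  cat(render_pyramid_text(x), sep = "\n")
  invisible(x)
}
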