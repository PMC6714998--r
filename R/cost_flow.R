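#' @title Cost flow accounting
#' @description Attach dollars to patient flows: what the cohort starting
#'   in each segment cost in years t and t+1, and what the up/stay/down
#'   movement groups cost, with percent changes.
#' @name cost_flow
NULL

#' Percent change between two dollar totals
#'
#' @param before Total at year t; must be positive.
#' @param after Total at year t+1.
#' @return Signed percentage, `100 * (after - before) / before`, unrounded.
#'   Round to integer percent only for display.
#' @examples
#' pct_change(1.8e6, 13.9e6)  # +672 at integer rounding
#' @export
pct_change <- function(before, after) {
  if (any(before <= 0)) stop("percent change undefined for non-positive base")
  100 * (after - before) / before
}

# shared core: joint cohort with year-t and year-t+1 costs and labels
joint_cohort <- function(panel, pyr_t, pyr_t1) {
  stopifnot(inherits(panel, "cost_panel"),
            inherits(pyr_t, "cost_pyramid"), inherits(pyr_t1, "cost_pyramid"))
  if (pyr_t1$fiscal_year != pyr_t$fiscal_year + 1L) {
    stop("pyramids must be for consecutive fiscal years")
  }
  m_t <- membership_vector(pyr_t)
  m_t1 <- membership_vector(pyr_t1)
  ids <- intersect(names(m_t), names(m_t1))
  if (length(ids) == 0L) stop("empty joint cohort for pair ",
                              pyr_t$fiscal_year, "->", pyr_t1$fiscal_year)
  c_t <- year_cost(panel, pyr_t$fiscal_year)
  c_t1 <- year_cost(panel, pyr_t1$fiscal_year)
  list(
    ids = ids,
    seg_t = m_t[ids], seg_t1 = m_t1[ids],
    cost_t = c_t[ids], cost_t1 = c_t1[ids],
    exiting_cost_t = round(sum(c_t[setdiff(names(m_t), ids)]), 2),
    entering_cost_t1 = round(sum(c_t1[setdiff(names(m_t1), ids)]), 2)
  )
}

flow_part <- function(group, cost_t, cost_t1, levels) {
  g <- factor(group, levels = levels)
  agg <- function(x) round(as.numeric(tapply(x, g, sum, default = 0)), 2)
  t0 <- agg(cost_t); t1 <- agg(cost_t1)
  data.frame(
    group = levels,
    n = as.integer(table(g)),
    cost_t = t0,
    cost_t1 = t1,
    pct_change = ifelse(t0 > 0, 100 * (t1 - t0) / t0, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Origin-segment cohort costs across a year pair
#'
#' For the joint cohort (patients with utilization in both years), groups
#' patients by their year-t segment and sums each group's year-t and
#' year-t+1 costs. Regression to the mean shows up here: the T-origin
#' cohort's costs typically fall while the B-origin cohort's rise.
#'
#' @param panel A [cost_panel].
#' @param pyr_t,pyr_t1 Pyramids for consecutive fiscal years.
#' @return data.frame with one row per origin segment (T, M, B): `n`,
#'   `cost_t`, `cost_t1`, `pct_change`.
#' @export
origin_cohort_costs <- function(panel, pyr_t, pyr_t1) {
  jc <- joint_cohort(panel, pyr_t, pyr_t1)
  flow_part(jc$seg_t, jc$cost_t, jc$cost_t1, SEGMENTS)
}

#' Movement-group costs across a year pair
#'
#' Classifies each joint-cohort patient as moving up, staying, or moving
#' down (segment order T > M > B) and sums each group's costs in both
#' years.
#'
#' @inheritParams origin_cohort_costs
#' @return data.frame with one row per movement group (up, stay, down).
#' @export
movement_group_costs <- function(panel, pyr_t, pyr_t1) {
  jc <- joint_cohort(panel, pyr_t, pyr_t1)
  dir <- ifelse(segment_rank(jc$seg_t1) > segment_rank(jc$seg_t), "up",
                ifelse(segment_rank(jc$seg_t1) < segment_rank(jc$seg_t),
                       "down", "stay"))
  flow_part(dir, jc$cost_t, jc$cost_t1, c("up", "stay", "down"))
}

#' Full cost-flow summary for a year pair
#'
#' Both partitions of the joint cohort — by origin segment and by movement
#' group — plus a reconciliation block with the cohort totals and the
#' dollars of patients present in only one of the two years, so every
#' figure reconciles with the per-year pyramid totals.
#'
#' @inheritParams origin_cohort_costs
#' @return Object of class `cost_flow_summary`: list with `pair`, `n_pair`,
#'   `origin`, `movement` (both data.frames), and `reconciliation`.
#' @export
cost_flow_summary <- function(panel, pyr_t, pyr_t1) {
  jc <- joint_cohort(panel, pyr_t, pyr_t1)
  origin <- origin_cohort_costs(panel, pyr_t, pyr_t1)
  movement <- movement_group_costs(panel, pyr_t, pyr_t1)
  structure(list(
    pair = c(pyr_t$fiscal_year, pyr_t1$fiscal_year),
    n_pair = length(jc$ids),
    origin = origin,
    movement = movement,
    reconciliation = list(
      joint_cost_t = round(sum(jc$cost_t), 2),
      joint_cost_t1 = round(sum(jc$cost_t1), 2),
      exiting_cost_t = jc$exiting_cost_t,
      entering_cost_t1 = jc$entering_cost_t1,
      pyramid_total_t = pyr_t$total_cost,
      pyramid_total_t1 = pyr_t1$total_cost
    )
  ), class = "cost_flow_summary")
}

#' @export
print.cost_flow_summary <- function(x, ...) {
  cat(sprintf("<cost_flow_summary> FY%d -> FY%d, joint cohort n = %d\n",
              x$pair[1] %% 100, x$pair[2] %% 100, x$n_pair))
  cat("origin segments:\n"); print(x$origin)
  cat("movement groups:\n"); print(x$movement)
  invisible(x)
}
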