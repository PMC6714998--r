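#' @title End-to-end study report
#' @description Chain segmentation, flow estimation, cost-flow accounting
#'   and trend fitting over a whole panel into one machine-readable report.
#' @name report
NULL

# p-value display in the house style: ".003", "<.001", ".02"
format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) return("<.001")
  if (p < 0.01) return(sub("^0", "", sprintf("%.3f", p)))
  sub("^0", "", sprintf("%.2f", p))
}

#' Run the full cost-pyramid analysis pipeline
#'
#' Builds a cost acuity pyramid for every fiscal year in the panel,
#' estimates transition counts/matrices and cost flows for every
#' consecutive year pair, averages the pair matrices into the study
#' Markov chain, aggregates movement both from the averaged matrix (with
#' nominal 5/45/50 shares) and from pooled observed counts, and fits the
#' four annual-total trends. Deterministic given the panel.
#'
#' @param panel A [cost_panel] spanning at least 2 fiscal years.
#' @param attributes Optional attribute data.frame for
#'   [compare_groups()] on the most recent year pair.
#' @return Object of class `study_report`: list with `schema_version`,
#'   `provenance`, `years`, `pyramids`, `pairs` (per pair: counts, matrix,
#'   movement, cost flow), `averaged_matrix`, `movement_from_matrix`,
#'   `stationary`, `trends`, and optionally `group_comparison`.
#' @export
run_pipeline <- function(panel, attributes = NULL) {
  stopifnot(inherits(panel, "cost_panel"))
  panel <- filter_utilizers(panel)
  yrs <- panel_years(panel)
  if (length(yrs) < 2L) stop("panel must span at least 2 fiscal years")
  if (any(diff(yrs) != 1L)) stop("panel years must be consecutive")

  pyramids <- lapply(yrs, function(y) build_pyramid(panel, y))
  names(pyramids) <- as.character(yrs)

  pairs <- list()
  for (i in seq_len(length(yrs) - 1L)) {
    pt <- pyramids[[i]]; pt1 <- pyramids[[i + 1L]]
    counts <- pair_transitions(pt, pt1)
    pairs[[paste0(yrs[i], "->", yrs[i + 1L])]] <- list(
      counts = counts,
      matrix = row_normalize(counts),
      movement = movement_counts(counts),
      cost_flow = cost_flow_summary(panel, pt, pt1)
    )
  }
  avg <- average_matrix(lapply(pairs, `[[`, "matrix"))

  report <- list(
    schema_version = "1.0",
    provenance = list(
      tool = paste0("costpyramid ",
                    as.character(utils::packageVersion("costpyramid"))),
      n_records = nrow(panel),
      n_patients = length(unique(panel$patient_id)),
      panel_total_cost = round(sum(panel$total_cost), 2)
    ),
    years = yrs,
    pyramids = pyramids,
    pairs = pairs,
    averaged_matrix = avg,
    movement_from_matrix = aggregate_movement(avg),
    stationary = tryCatch(stationary_distribution(avg),
                          error = function(e) NULL),
    trends = if (length(yrs) >= 3L) segment_trends(pyramids) else NULL
  )
  if (!is.null(attributes)) {
    k <- length(yrs)
    report$group_comparison <- compare_groups(
      panel, pyramids[[k - 1L]], pyramids[[k]], attributes)
  }
  structure(report, class = "study_report")
}

#' Plain-text rendering of a cost acuity pyramid
#'
#' Three fixed-width tiers with segment sizes, cost thresholds, dollar
#' totals (US $M) and shares of the year's total.
#'
#' @param pyramid A `cost_pyramid`.
#' @return Character vector of lines.
#' @export
render_pyramid_text <- function(pyramid) {
  stopifnot(inherits(pyramid, "cost_pyramid"))
  musd <- function(x) sprintf("US $%.1fM", x / 1e6)
  shr <- function(s) {
    v <- pyramid$segment_shares[[s]]
    if (is.na(v)) "-" else sprintf("%d%%", round_half_away(100 * v))
  }
  thr <- function(s) {
    v <- pyramid$thresholds[[s]]
    if (is.na(v)) "-" else sprintf(">= US $%s", format(round(v), big.mark = ","))
  }
  tier <- function(pad, s, pct, extra) {
    sprintf("%s[ %s | %3s | n=%-5d | %s | %s%s ]",
            strrep(" ", pad), s, pct, pyramid$segment_sizes[[s]],
            musd(pyramid$segment_totals[[s]]), shr(s), extra)
  }
  c(sprintf("Cost acuity pyramid, FY%d (n = %d, total %s)",
            pyramid$fiscal_year, pyramid$n, musd(pyramid$total_cost)),
    tier(8, "T", "5%", paste0(" | ", thr("T"))),
    tier(4, "M", "45%", paste0(" | ", thr("M"))),
    tier(0, "B", "50%", ""))
}

#' Serialize a study report (or any result object) to JSON
#'
#' Raw unrounded values are written; display rounding is a presentation
#' concern. Matrices become row-major nested arrays with T/M/B labels.
#'
#' @param report A `study_report` (or any jsonlite-serializable list).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

# strip S3 classes / attributes into plain lists for JSON
report_to_list <- function(x) {
  if (inherits(x, "transition_matrix") || inherits(x, "matrix") ||
      is.matrix(x)) {
    m <- unclass(x)
    attr(m, "provenance") <- NULL
    return(lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])))
  }
  if (inherits(x, "cost_pyramid")) {
    x <- unclass(x)
    x$membership <- NULL   # bulky; memberships go to CSV via the CLI
  }
  if (inherits(x, "table")) return(as.list(as.data.frame(x)))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), report_to_list))
  x
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> FY%d-FY%d, %d patients, %d pairs\n",
              min(x$years), max(x$years),
              x$provenance$n_patients, length(x$pairs)))
  print(x$averaged_matrix)
  print(x$movement_from_matrix)
  invisible(x)
}
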