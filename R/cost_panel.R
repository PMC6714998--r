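#' Construct a patient-year cost panel
#'
#' A cost panel is the atomic data structure of the package: one row per
#' patient per fiscal year, with inpatient and outpatient hospital costs in
#' US dollars. Annual total cost is the sum of the two components, carried
#' at cent precision. Fiscal years are plain integer labels (e.g. `2015`
#' for the accounting year beginning Oct 1, 2014); no calendar arithmetic
#' is performed.
#'
#' @param records A data.frame with columns `patient_id`, `fiscal_year`,
#'   `inpatient_cost`, `outpatient_cost` and optionally `total_cost`. If
#'   `total_cost` is present it must equal the component sum to the cent;
#'   if absent it is computed.
#' @return An object of class `cost_panel` (a data.frame) with the five
#'   canonical columns, rows sorted by `(patient_id, fiscal_year)`.
#' @examples
#' p <- cost_panel(data.frame(
#'   patient_id = c("p1", "p1", "p2"),
#'   fiscal_year = c(2011L, 2012L, 2011L),
#'   inpatient_cost = c(100, 0, 10),
#'   outpatient_cost = c(50, 0, 0)))
#' panel_years(p)
#' @export
cost_panel <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("patient_id", "fiscal_year", "inpatient_cost", "outpatient_cost")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    patient_id      = as.character(records$patient_id),
    fiscal_year     = as.integer(records$fiscal_year),
    inpatient_cost  = round(as.numeric(records$inpatient_cost), 2),
    outpatient_cost = round(as.numeric(records$outpatient_cost), 2),
    stringsAsFactors = FALSE
  )
  if (anyNA(df)) stop("panel contains missing values")
  bad <- which(df$inpatient_cost < 0 | df$outpatient_cost < 0)
  if (length(bad) > 0L) {
    stop("negative cost at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  df$total_cost <- round(df$inpatient_cost + df$outpatient_cost, 2)
  if ("total_cost" %in% names(records)) {
    given <- round(as.numeric(records$total_cost), 2)
    off <- which(abs(given - df$total_cost) > 0.005)
    if (length(off) > 0L) {
      stop("total_cost != inpatient_cost + outpatient_cost at row(s): ",
           paste(utils::head(off, 5), collapse = ", "))
    }
  }
  key <- paste(df$patient_id, df$fiscal_year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (patient_id, fiscal_year) key: (",
         sub("\r", ", ", dup, fixed = TRUE), ")")
  }
  df <- df[order(df$patient_id, df$fiscal_year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("cost_panel", "data.frame"))
}

#' Fiscal years present in a panel
#'
#' @param panel A `cost_panel`.
#' @return Sorted integer vector of fiscal-year labels.
#' @export
panel_years <- function(panel) {
  stopifnot(inherits(panel, "cost_panel"))
  sort(unique(panel$fiscal_year))
}

#' @export
print.cost_panel <- function(x, ...) {
  yrs <- panel_years(x)
  cat(sprintf("<cost_panel> %d records, %d patients, FY%s-FY%s\n",
              nrow(x), length(unique(x$patient_id)),
              min(yrs) %% 100, max(yrs) %% 100))
  NextMethod()
}

#' Read a cost panel from a delimited text file
#'
#' Expects a header row. Column names can be remapped via `schema`, so
#' exports from a warehouse with other headers can be read directly.
#' Duplicate `(patient, year)` rows are an error: the panel is annualized
#' already, and silent aggregation would hide upstream extraction bugs.
#'
#' @param path File to read.
#' @param schema Optional named character vector mapping canonical column
#'   names (`patient_id`, `fiscal_year`, `inpatient_cost`,
#'   `outpatient_cost`) to the names used in the file, e.g.
#'   `c(patient_id = "MRN", fiscal_year = "FY")`.
#' @param delim Field delimiter, default comma.
#' @return A [cost_panel].
#' @export
read_panel <- function(path, schema = NULL, delim = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c(patient_id = "patient_id", fiscal_year = "fiscal_year",
              inpatient_cost = "inpatient_cost",
              outpatient_cost = "outpatient_cost")
  if (!is.null(schema)) wanted[names(schema)] <- schema
  absent <- wanted[!(wanted %in% names(raw))]
  if (length(absent) > 0L) {
    stop("column(s) not found in ", path, ": ",
         paste(sprintf("%s (for %s)", absent, names(absent)), collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[wanted[[col]]]]))
    if (anyNA(v)) {
      stop("unparseable ", col, " at row(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    }
    v
  }
  cost_panel(data.frame(
    patient_id      = raw[[wanted[["patient_id"]]]],
    fiscal_year     = num("fiscal_year"),
    inpatient_cost  = num("inpatient_cost"),
    outpatient_cost = num("outpatient_cost"),
    stringsAsFactors = FALSE
  ))
}

#' Write a cost panel to a delimited text file
#'
#' Costs are serialized with two decimal places; rows are ordered by
#' `(patient_id, fiscal_year)` so repeated writes of the same panel are
#' byte-identical and `read_panel(write_panel(p)) == p`.
#'
#' @param panel A `cost_panel`.
#' @param path Destination file.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, delim = ",") {
  stopifnot(inherits(panel, "cost_panel"))
  out <- data.frame(
    patient_id      = panel$patient_id,
    fiscal_year     = panel$fiscal_year,
    inpatient_cost  = sprintf("%.2f", panel$inpatient_cost),
    outpatient_cost = sprintf("%.2f", panel$outpatient_cost),
    total_cost      = sprintf("%.2f", panel$total_cost),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# A patient-year counts as utilization only if a component cost is positive;
# a literal all-zero row is tolerated on input but never enters a pyramid.
has_utilization <- function(panel) {
  panel$inpatient_cost > 0 | panel$outpatient_cost > 0
}

#' Drop patients with no health care utilization in the whole panel
#'
#' Patients whose costs are zero in every recorded year carry no variation
#' and are excluded from the study population. Idempotent.
#'
#' @param panel A `cost_panel`.
#' @return A `cost_panel` containing only patients with positive summed
#'   total cost across all their years.
#' @export
filter_utilizers <- function(panel) {
  stopifnot(inherits(panel, "cost_panel"))
  sums <- tapply(panel$total_cost, panel$patient_id, sum)
  keep <- names(sums)[sums > 0]
  out <- panel[panel$patient_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cost_panel", "data.frame"))
}

#' Annual cost of every patient recorded in one fiscal year
#'
#' @param panel A `cost_panel`.
#' @param fiscal_year A year label present in the panel.
#' @return Named numeric vector, `patient_id -> total_cost`, for patients
#'   with a record in that year (zero-cost records included). Patients
#'   with no record that year are absent.
#' @export
year_cost <- function(panel, fiscal_year) {
  stopifnot(inherits(panel, "cost_panel"))
  yrs <- panel_years(panel)
  if (!(fiscal_year %in% yrs)) {
    stop("fiscal year ", fiscal_year, " not in panel (available: ",
         paste(yrs, collapse = ", "), ")")
  }
  sub <- panel[panel$fiscal_year == fiscal_year, , drop = FALSE]
  stats::setNames(sub$total_cost, sub$patient_id)
}
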