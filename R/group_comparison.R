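#' @title Movement-group comparisons
#' @description Compare patient characteristics across the moved-up /
#'   stayed / moved-down groups: chi-square tests of independence for
#'   categorical attributes, one-way ANOVA for continuous ones.
#' @name group_comparison
NULL

#' Pearson chi-square test of independence on a contingency table
#'
#' No continuity correction and no multiple-testing adjustment, matching
#' the conventional unadjusted per-attribute presentation.
#'
#' @param counts Non-negative integer matrix (rows = groups, columns =
#'   categories), at least 2x2, with positive row and column margins.
#' @return List with `statistic`, `df` (`(r-1)(c-1)`), `p_value` and the
#'   `expected` counts.
#' @export
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need at least 2 groups and 2 categories")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       expected = ht$expected)
}

#' One-way ANOVA reconstructed from per-group summaries
#'
#' Computes the between- and within-group sums of squares from group
#' sizes, means and sample SDs — no raw data needed — and tests with the
#' F distribution. Equivalent to `anova(lm(...))` on the raw data when
#' the summaries come from that data; for two groups F equals the square
#' of the pooled-variance t statistic.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group sample SDs (>= 0).
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
anova_from_summaries <- function(n, mean, sd) {
  if (!(length(n) == length(mean) && length(n) == length(sd))) {
    stop("n, mean, sd must have equal length")
  }
  if (length(n) < 2L) stop("need at least 2 groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(sd < 0)) stop("sd must be non-negative")
  k <- length(n)
  N <- sum(n)
  grand <- sum(n * mean) / N
  ss_between <- sum(n * (mean - grand)^2)
  ss_within <- sum((n - 1) * sd^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ss_within == 0) {
    # no within-group variability: any mean difference is infinitely strong
    F <- if (ss_between == 0) 0 else Inf
  } else {
    F <- (ss_between / df1) / (ss_within / df2)
  }
  list(F = F, df1 = df1, df2 = df2,
       p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# per-patient movement group (up/stay/down) over a consecutive year pair
movement_groups <- function(pyr_t, pyr_t1) {
  m_t <- membership_vector(pyr_t)
  m_t1 <- membership_vector(pyr_t1)
  ids <- intersect(names(m_t), names(m_t1))
  if (length(ids) == 0L) stop("empty joint cohort")
  dir <- ifelse(segment_rank(m_t1[ids]) > segment_rank(m_t[ids]), "up",
                ifelse(segment_rank(m_t1[ids]) < segment_rank(m_t[ids]),
                       "down", "stay"))
  factor(stats::setNames(dir, ids), levels = c("up", "stay", "down"))
}

#' Compare attributes across movement groups for a year pair
#'
#' Classifies the joint cohort of two consecutive pyramids into moved-up /
#' stayed / moved-down, then tests each attribute column for association
#' with group: numeric columns by one-way ANOVA (via per-group summaries),
#' everything else by a chi-square test of independence. Missing values
#' are excluded per attribute, so each attribute reports its own N.
#' Categorical attributes with more than two levels additionally get
#' per-category tests (each category versus the rest).
#'
#' @param panel A [cost_panel] (used for cohort construction only).
#' @param pyr_t,pyr_t1 Pyramids for consecutive fiscal years.
#' @param attributes data.frame with a `patient_id` column and one column
#'   per attribute; `NA` means unknown.
#' @return Object of class `group_comparison`: list with `pair`, `n`,
#'   `groups` (per-group sizes) and `attributes`, a named list holding per
#'   attribute its `type`, `n_known`, summary `table` (counts and column
#'   percentages, or mean/SD per group), `p_value`, and `per_category`
#'   p-values where applicable.
#' @export
compare_groups <- function(panel, pyr_t, pyr_t1, attributes) {
  stopifnot(is.data.frame(attributes), "patient_id" %in% names(attributes))
  grp <- movement_groups(pyr_t, pyr_t1)
  ids <- names(grp)
  rows <- match(ids, as.character(attributes$patient_id))
  out <- list(pair = c(pyr_t$fiscal_year, pyr_t1$fiscal_year),
              n = length(ids),
              groups = table(grp),
              attributes = list())
  for (att in setdiff(names(attributes), "patient_id")) {
    v <- attributes[[att]][rows]
    known <- !is.na(v)
    g <- grp[known]; v <- v[known]
    if (sum(known) == 0L || nlevels(droplevels(g)) < 2L) next
    if (is.numeric(v)) {
      n_g <- as.integer(table(g))
      keep <- n_g >= 2
      m_g <- as.numeric(tapply(v, g, mean))
      s_g <- as.numeric(tapply(v, g, stats::sd))
      test <- anova_from_summaries(n_g[keep], m_g[keep], s_g[keep])
      out$attributes[[att]] <- list(
        type = "numeric", n_known = sum(known),
        table = data.frame(group = levels(g)[keep], n = n_g[keep],
                           mean = m_g[keep], sd = s_g[keep]),
        p_value = test$p_value, statistic = test$F)
    } else {
      v <- factor(as.character(v))
      tab <- table(g, v)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      test <- chisq_independence(tab)
      per_cat <- NULL
      if (ncol(tab) > 2L) {
        per_cat <- vapply(colnames(tab), function(cat) {
          two <- cbind(tab[, cat], rowSums(tab) - tab[, cat])
          chisq_independence(two)$p_value
        }, 0)
      }
      out$attributes[[att]] <- list(
        type = "categorical", n_known = sum(known),
        table = tab, p_value = test$p_value, statistic = test$statistic,
        per_category = per_cat)
    }
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> FY%d -> FY%d, N = %d (up %d / stay %d / down %d)\n",
              x$pair[1] %% 100, x$pair[2] %% 100, x$n,
              x$groups[["up"]], x$groups[["stay"]], x$groups[["down"]]))
  for (att in names(x$attributes)) {
    a <- x$attributes[[att]]
    cat(sprintf("  %-20s %-11s N=%-5d p = %s\n", att, a$type, a$n_known,
                format_p(a$p_value)))
  }
  invisible(x)
}
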