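#' @title Patient flow between cost segments
#' @description Estimate year-pair transition counts and probabilities over
#'   the T/M/B segments, average pair matrices into a study-level Markov
#'   chain, and aggregate movement into up/stay/down fractions.
#' @name flow_analysis
NULL

#' Transition counts between two years' segment memberships
#'
#' Counts are taken over the intersection of the two cohorts: a patient
#' contributes only if present (a utilizer) in both years. Patients seen
#' in one year only are tallied separately in the result so the cohort
#' construction is never hidden.
#'
#' @param labels_t,labels_t1 Named character vectors (`patient_id` ->
#'   segment label among T/M/B) for year t and year t+1.
#' @param pair Integer vector `c(t, t+1)` naming the year pair.
#' @return Object of class `transition_counts`: list with `pair`, `counts`
#'   (3x3 integer matrix, rows = from-segment, cols = to-segment),
#'   `n_pair`, `n_only_t`, `n_only_t1`.
#' @export
transition_counts <- function(labels_t, labels_t1, pair) {
  stopifnot(length(pair) == 2L)
  if (!all(labels_t %in% SEGMENTS) || !all(labels_t1 %in% SEGMENTS)) {
    stop("segment labels must be among T, M, B")
  }
  joint <- intersect(names(labels_t), names(labels_t1))
  counts <- table(
    factor(labels_t[joint], levels = SEGMENTS),
    factor(labels_t1[joint], levels = SEGMENTS)
  )
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(from = SEGMENTS, to = SEGMENTS))
  structure(list(
    pair = as.integer(pair),
    counts = counts,
    n_pair = length(joint),
    n_only_t = length(setdiff(names(labels_t), joint)),
    n_only_t1 = length(setdiff(names(labels_t1), joint))
  ), class = "transition_counts")
}

#' Transition counts between two consecutive pyramids
#'
#' @param pyr_t,pyr_t1 `cost_pyramid` objects for consecutive fiscal years.
#' @return A [transition_counts] object.
#' @export
pair_transitions <- function(pyr_t, pyr_t1) {
  stopifnot(inherits(pyr_t, "cost_pyramid"), inherits(pyr_t1, "cost_pyramid"))
  if (pyr_t1$fiscal_year != pyr_t$fiscal_year + 1L) {
    stop("pyramids must be for consecutive fiscal years (got ",
         pyr_t$fiscal_year, " and ", pyr_t1$fiscal_year, ")")
  }
  transition_counts(membership_vector(pyr_t), membership_vector(pyr_t1),
                    c(pyr_t$fiscal_year, pyr_t1$fiscal_year))
}

new_transition_matrix <- function(probs, provenance) {
  dimnames(probs) <- list(from = SEGMENTS, to = SEGMENTS)
  structure(probs, class = c("transition_matrix", "matrix"),
            provenance = provenance)
}

#' Row-normalize transition counts into a transition matrix
#'
#' @param counts A [transition_counts] object.
#' @return A row-stochastic 3x3 `transition_matrix` whose `provenance`
#'   attribute records the year pair.
#' @export
row_normalize <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  rs <- rowSums(counts$counts)
  empty <- SEGMENTS[rs == 0]
  if (length(empty) > 0L) {
    stop("no patients observed leaving segment(s) ",
         paste(empty, collapse = ", "), " in pair ",
         paste(counts$pair, collapse = "->"))
  }
  new_transition_matrix(counts$counts / rs,
                        provenance = paste(counts$pair, collapse = "->"))
}

#' Average a list of transition matrices element-wise
#'
#' The study-level Markov chain is the unweighted mean of the per-pair
#' probability matrices (not pooled counts), so each year pair carries
#' equal weight regardless of cohort size.
#'
#' @param matrices Non-empty list of `transition_matrix` objects.
#' @return A `transition_matrix`; its `provenance` lists the input pairs.
#' @export
average_matrix <- function(matrices) {
  if (length(matrices) == 0L) stop("need at least one matrix to average")
  for (m in matrices) validate_transition_matrix(m)
  avg <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  new_transition_matrix(avg, provenance = paste(
    vapply(matrices, function(m) attr(m, "provenance") %||% "?", ""),
    collapse = ", "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a plain matrix to a transition matrix
#'
#' @param probs 3x3 row-stochastic matrix with rows/cols ordered T, M, B.
#' @param provenance Free-text provenance label.
#' @return A `transition_matrix`.
#' @export
as_transition_matrix <- function(probs, provenance = "user") {
  probs <- as.matrix(probs)
  m <- new_transition_matrix(probs, provenance)
  validate_transition_matrix(m)
  m
}

validate_transition_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L))) {
    stop("transition matrix must be 3x3")
  }
  if (any(m < 0) || any(m > 1)) stop("transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > 1e-9)) stop("transition matrix rows must sum to 1")
  invisible(m)
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("<transition_matrix> (", attr(x, "provenance"), ")\n", sep = "")
  m <- unclass(x)
  attr(m, "provenance") <- NULL
  print(round(m, digits))
  invisible(x)
}

new_movement_summary <- function(frac, counts = NULL, n = NULL) {
  structure(list(frac_up = unname(frac[["up"]]),
                 frac_stay = unname(frac[["stay"]]),
                 frac_down = unname(frac[["down"]]),
                 counts = counts, n = n),
            class = "movement_summary")
}

# classify each (from, to) cell as up / stay / down under T > M > B
movement_class <- function() {
  from <- segment_rank(rep(SEGMENTS, times = 3))
  to <- segment_rank(rep(SEGMENTS, each = 3))
  cls <- ifelse(to > from, "up", ifelse(to < from, "down", "stay"))
  matrix(cls, 3, 3, dimnames = list(from = SEGMENTS, to = SEGMENTS))
}

#' Aggregate a transition matrix into up/stay/down fractions
#'
#' Triangular decomposition: each transition probability is weighted by the
#' share of the population sitting in its from-segment and the nine terms
#' are summed by direction. With the nominal pyramid shares
#' (T, M, B) = (0.05, 0.45, 0.50) this reproduces the study-level yearly
#' movement fractions.
#'
#' @param matrix A `transition_matrix`.
#' @param segment_shares Probability 3-vector over (T, M, B); named or in
#'   that order. Defaults to the nominal pyramid shares.
#' @return A `movement_summary` with `frac_up`, `frac_stay`, `frac_down`
#'   summing to 1.
#' @examples
#' m <- as_transition_matrix(rbind(c(.24, .54, .22),
#'                                 c(.05, .55, .40),
#'                                 c(.02, .29, .69)))
#' aggregate_movement(m)  # ~18% up, 60% stay, 22% down
#' @export
aggregate_movement <- function(matrix, segment_shares = c(T = 0.05, M = 0.45, B = 0.50)) {
  validate_transition_matrix(matrix)
  shares <- as.numeric(segment_shares)
  if (!is.null(names(segment_shares))) {
    if (!setequal(names(segment_shares), SEGMENTS)) {
      stop("segment_shares names must be T, M, B")
    }
    shares <- as.numeric(segment_shares[SEGMENTS])
  }
  if (length(shares) != 3L || any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
    stop("segment_shares must be a probability 3-vector over (T, M, B)")
  }
  weighted <- shares * unclass(matrix)   # row-wise weighting
  cls <- movement_class()
  frac <- vapply(c(up = "up", stay = "stay", down = "down"),
                 function(d) sum(weighted[cls == d]), 0)
  new_movement_summary(frac)
}

#' Up/stay/down counts and fractions from observed transitions
#'
#' @param pair A [transition_counts] object with `n_pair > 0`.
#' @return A `movement_summary` with integer `counts` and fractions over
#'   `n_pair`.
#' @export
movement_counts <- function(pair) {
  stopifnot(inherits(pair, "transition_counts"))
  if (pair$n_pair == 0L) stop("empty joint cohort: no patients in both years")
  cls <- movement_class()
  cnt <- vapply(c(up = "up", stay = "stay", down = "down"),
                function(d) sum(pair$counts[cls == d]), 0L)
  new_movement_summary(cnt / pair$n_pair, counts = cnt, n = pair$n_pair)
}

#' @export
print.movement_summary <- function(x, ...) {
  pct <- function(f) sprintf("%d%%", round_half_away(100 * f))
  cat(sprintf("<movement_summary> up %s, stay %s, down %s",
              pct(x$frac_up), pct(x$frac_stay), pct(x$frac_down)))
  if (!is.null(x$counts)) {
    cat(sprintf("  (n = %d: %d/%d/%d)", x$n,
                x$counts[["up"]], x$counts[["stay"]], x$counts[["down"]]))
  }
  cat("\n")
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' The unique left eigenvector of an irreducible chain with eigenvalue 1,
#' normalized to a probability vector. A standard long-run diagnostic: the
#' segment occupancy the chain would settle into if the observed dynamics
#' persisted.
#'
#' @param matrix A `transition_matrix`; must be irreducible and aperiodic.
#' @return Named probability 3-vector over (T, M, B) with
#'   `pi %*% P == pi` within 1e-10.
#' @export
stationary_distribution <- function(matrix) {
  validate_transition_matrix(matrix)
  P <- unclass(matrix)
  # boolean reachability: chain is irreducible iff I + P + P^2 is all-positive
  reach <- (diag(3) + P) %*% (diag(3) + P)
  if (any(reach == 0)) {
    blocked <- which(reach == 0, arr.ind = TRUE)[1L, ]
    stop("chain is reducible: segment ", SEGMENTS[blocked[1L]],
         " cannot reach segment ", SEGMENTS[blocked[2L]])
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-8) stop("no unit eigenvalue found")
  v <- Re(e$vectors[, i])
  pi <- v / sum(v)
  if (max(abs(as.numeric(pi %*% P) - pi)) > 1e-10) {
    stop("stationary distribution failed to converge (periodic chain?)")
  }
  stats::setNames(pi, SEGMENTS)
}

# round half away from zero, used for all printed integer percentages
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
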