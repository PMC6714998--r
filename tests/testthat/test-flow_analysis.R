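test_that("pair transitions count moves over the joint cohort only", {
  lab_t <- c(a = "T", b = "M", c = "M", d = "B", e = "B", f = "B")
  lab_t1 <- c(a = "M", b = "M", c = "T", d = "B", e = "M", g = "B")
  tc <- transition_counts(lab_t, lab_t1, c(2014L, 2015L))
  # hand enumeration: a T->M, b M->M, c M->T, d B->B, e B->M; f/g unmatched
  expect_equal(tc$n_pair, 5L)
  expect_equal(tc$n_only_t, 1L)
  expect_equal(tc$n_only_t1, 1L)
  expect_equal(tc$counts["T", "M"], 1L)
  expect_equal(tc$counts["M", "M"], 1L)
  expect_equal(tc$counts["M", "T"], 1L)
  expect_equal(tc$counts["B", "B"], 1L)
  expect_equal(tc$counts["B", "M"], 1L)
  expect_equal(sum(tc$counts), tc$n_pair)

  # identical memberships -> diagonal only
  same <- transition_counts(lab_t, lab_t, c(2014L, 2015L))
  expect_equal(sum(diag(same$counts)), same$n_pair)
  expect_equal(sum(same$counts) - sum(diag(same$counts)), 0L)

  # pyramid interface enforces consecutive years
  p <- random_panel(100, years = c(2011:2012, 2014L), seed = 1)
  expect_error(pair_transitions(build_pyramid(p, 2012), build_pyramid(p, 2014)),
               "consecutive")
  tc2 <- pair_transitions(build_pyramid(p, 2011), build_pyramid(p, 2012))
  expect_equal(tc2$n_pair, 100L)
  expect_equal(sum(tc2$counts), 100L)
})

test_that("row_normalize yields row-stochastic matrices and flags empty rows", {
  lab_t <- stats::setNames(rep(c("T", "M", "B"), c(50, 100, 100)),
                           sprintf("p%03d", 1:250))
  set.seed(3)
  lab_t1 <- stats::setNames(sample(c("T", "M", "B"), 250, TRUE), names(lab_t))
  m <- row_normalize(transition_counts(lab_t, lab_t1, c(2011L, 2012L)))
  expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(m >= 0 & m <= 1))

  # arithmetic on a known T row: 6/27/17 of 50
  lab_known <- c(rep("T", 50), rep("M", 1), rep("B", 1))
  names(lab_known) <- sprintf("q%03d", 1:52)
  to <- c(rep("T", 6), rep("M", 27), rep("B", 17), "M", "B")
  names(to) <- names(lab_known)
  mk <- row_normalize(transition_counts(lab_known, to, c(2011L, 2012L)))
  expect_equal(unname(mk["T", ]), c(0.12, 0.54, 0.34))

  # no one observed leaving T -> degenerate pair error naming T
  lab_no_t <- c(a = "M", b = "B")
  expect_error(row_normalize(transition_counts(lab_no_t, lab_no_t,
                                               c(2011L, 2012L))),
               "T")
})

test_that("average_matrix is the unweighted element-wise mean", {
  pm <- paper_matrix()
  expect_equal(unclass(average_matrix(list(pm, pm, pm, pm))), unclass(pm),
               ignore_attr = TRUE)
  # identity-with-uniform hand case: rows (2/3, 1/6, 1/6) etc.
  ident <- as_transition_matrix(diag(3))
  unif <- as_transition_matrix(matrix(1 / 3, 3, 3))
  avg <- average_matrix(list(ident, unif))
  expect_equal(unname(diag(avg)), rep(2 / 3, 3))
  expect_equal(unname(avg[1, 2]), 1 / 6)
  expect_equal(unname(rowSums(avg)), rep(1, 3), tolerance = 1e-12)
  expect_error(average_matrix(list()), "at least one")
})

test_that("aggregate_movement implements the triangular decomposition", {
  # independent brute force over the 9 (from, to) cells
  brute <- function(P, shares) {
    rank <- c(T = 3, M = 2, B = 1)
    res <- c(up = 0, stay = 0, down = 0)
    for (from in c("T", "M", "B")) for (to in c("T", "M", "B")) {
      d <- if (rank[[to]] > rank[[from]]) "up"
           else if (rank[[to]] < rank[[from]]) "down" else "stay"
      res[[d]] <- res[[d]] + shares[[from]] * P[from, to]
    }
    res
  }
  set.seed(21)
  for (i in 1:20) {
    P <- matrix(stats::rgamma(9, 1), 3, 3)
    P <- as_transition_matrix(P / rowSums(P))
    s <- stats::rgamma(3, 1); s <- stats::setNames(s / sum(s), c("T", "M", "B"))
    mv <- aggregate_movement(P, s)
    b <- brute(P, s)
    expect_equal(c(mv$frac_up, mv$frac_stay, mv$frac_down),
                 unname(b[c("up", "stay", "down")]), tolerance = 1e-12)
    expect_equal(mv$frac_up + mv$frac_stay + mv$frac_down, 1, tolerance = 1e-9)
  }
  ident <- as_transition_matrix(diag(3))
  mv <- aggregate_movement(ident, c(T = 0.2, M = 0.3, B = 0.5))
  expect_equal(c(mv$frac_up, mv$frac_stay, mv$frac_down), c(0, 1, 0))
  expect_error(aggregate_movement(paper_matrix(), c(0.5, 0.5, 0.5)),
               "probability")
})

test_that("movement_counts classifies cells and agrees with per-patient brute force", {
  lab_t <- c(a = "T", b = "M", c = "M", d = "B", e = "B", f = "B",
             g = "M", h = "B", i = "T", j = "B")
  set.seed(8)
  lab_t1 <- stats::setNames(sample(c("T", "M", "B"), 10, TRUE), names(lab_t))
  tc <- transition_counts(lab_t, lab_t1, c(2011L, 2012L))
  mv <- movement_counts(tc)
  rank <- c(T = 3, M = 2, B = 1)
  dirs <- ifelse(rank[lab_t1] > rank[lab_t], "up",
                 ifelse(rank[lab_t1] < rank[lab_t], "down", "stay"))
  expect_equal(unname(mv$counts),
               unname(c(sum(dirs == "up"), sum(dirs == "stay"),
                        sum(dirs == "down"))))
  expect_equal(mv$frac_up + mv$frac_stay + mv$frac_down, 1, tolerance = 1e-9)

  diag_only <- transition_counts(lab_t, lab_t, c(2011L, 2012L))
  mvd <- movement_counts(diag_only)
  expect_equal(mvd$counts[["stay"]], mvd$n)
  expect_equal(c(mvd$frac_up, mvd$frac_stay, mvd$frac_down), c(0, 1, 0))
})

test_that("matrix aggregation and observed counts agree when shares come from the counts", {
  set.seed(12)
  n <- 500
  lab_t <- stats::setNames(sample(c("T", "M", "B"), n, TRUE, c(.1, .4, .5)),
                           sprintf("p%03d", 1:n))
  lab_t1 <- stats::setNames(sample(c("T", "M", "B"), n, TRUE), names(lab_t))
  tc <- transition_counts(lab_t, lab_t1, c(2011L, 2012L))
  shares <- stats::setNames(rowSums(tc$counts) / tc$n_pair, c("T", "M", "B"))
  from_matrix <- aggregate_movement(row_normalize(tc), shares)
  from_counts <- movement_counts(tc)
  expect_equal(from_matrix$frac_up, from_counts$frac_up, tolerance = 1e-12)
  expect_equal(from_matrix$frac_stay, from_counts$frac_stay, tolerance = 1e-12)
  expect_equal(from_matrix$frac_down, from_counts$frac_down, tolerance = 1e-12)
})

test_that("stationary distribution is the fixed point of an irreducible chain", {
  unif <- as_transition_matrix(matrix(1 / 3, 3, 3))
  expect_equal(unname(stationary_distribution(unif)), rep(1 / 3, 3),
               tolerance = 1e-12)

  pi <- stationary_distribution(paper_matrix())
  # power-iteration oracle
  v <- c(1, 0, 0)
  P <- unclass(paper_matrix())
  for (i in 1:10000) v <- as.numeric(v %*% P)
  expect_equal(unname(pi), v, tolerance = 1e-10)
  expect_equal(as.numeric(pi %*% P), unname(pi), tolerance = 1e-10)

  expect_error(stationary_distribution(as_transition_matrix(diag(3))),
               "reducible")
})
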