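test_that("chi-square matches the direct formula and handles degenerate tables", {
  # table equal to its own expected counts -> statistic 0, p = 1
  flat <- matrix(c(10, 20, 20, 40), 2, 2)
  res <- chisq_independence(flat)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # direct-formula oracle on random 3x2 tables
  set.seed(19)
  for (i in 1:15) {
    tab <- matrix(stats::rpois(6, 30) + 1, 3, 2)
    res <- chisq_independence(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_equal(res$statistic, stat, tolerance = 1e-12)
    expect_equal(res$df, 2)
    expect_equal(res$p_value, stats::pchisq(stat, 2, lower.tail = FALSE),
                 tolerance = 1e-12)
    # permutation invariance
    perm <- chisq_independence(tab[c(2, 3, 1), c(2, 1)])
    expect_equal(perm$statistic, res$statistic, tolerance = 1e-12)
  }
  expect_error(chisq_independence(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
  expect_error(chisq_independence(matrix(1:3, 3, 1)), "at least 2")
})

test_that("the published live-alone contingency counts give p rounding to .02", {
  tab <- rbind(up = c(yes = 375, no = 28),
               stay = c(yes = 1255, no = 72),
               down = c(yes = 449, no = 44))
  res <- chisq_independence(tab)
  expect_equal(round(res$p_value, 2), 0.02)
})

test_that("ANOVA from summaries matches raw-data ANOVA and the t^2 identity", {
  set.seed(27)
  g <- rep(1:3, c(12, 15, 9))
  y <- stats::rnorm(36, mean = c(0, 0.5, 1)[g])
  n <- as.integer(table(g))
  m <- as.numeric(tapply(y, g, mean))
  s <- as.numeric(tapply(y, g, stats::sd))
  res <- anova_from_summaries(n, m, s)
  raw <- stats::anova(stats::lm(y ~ factor(g)))
  expect_equal(res$F, raw$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, raw$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 33L)

  # two groups: F = t^2 for the pooled-variance t test
  y2 <- stats::rnorm(20); g2 <- rep(1:2, each = 10)
  tt <- stats::t.test(y2 ~ g2, var.equal = TRUE)
  res2 <- anova_from_summaries(c(10L, 10L),
                               as.numeric(tapply(y2, g2, mean)),
                               as.numeric(tapply(y2, g2, stats::sd)))
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-10)

  # identical group means -> F = 0, p = 1
  none <- anova_from_summaries(c(5L, 5L), c(2, 2), c(1, 1.5))
  expect_equal(none$F, 0)
  expect_equal(none$p_value, 1)
  expect_error(anova_from_summaries(c(1L, 5L), c(0, 1), c(1, 1)), "n >= 2")
})

test_that("null p-values from summary ANOVA are approximately uniform", {
  set.seed(55)
  reps <- 1000
  ps <- vapply(seq_len(reps), function(i) {
    y <- stats::rnorm(45)
    g <- rep(1:3, each = 15)
    anova_from_summaries(rep(15L, 3),
                         as.numeric(tapply(y, g, mean)),
                         as.numeric(tapply(y, g, stats::sd)))$p_value
  }, 0)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("compare_groups tallies a hand-built cohort and handles missing values", {
  # 12 patients, two years; costs pick segments deterministically (n=12 -> 0/6/6)
  ids <- sprintf("h%02d", 1:12)
  c14 <- stats::setNames(c(120, 110, 100, 90, 80, 70, 6, 5, 4, 3, 2, 1), ids)
  c15 <- stats::setNames(c(120, 110, 4, 3, 80, 70, 100, 90, 2, 1, 6, 5), ids)
  panel <- cost_panel(rbind(
    data.frame(patient_id = ids, fiscal_year = 2014L,
               inpatient_cost = unname(c14), outpatient_cost = 0),
    data.frame(patient_id = ids, fiscal_year = 2015L,
               inpatient_cost = unname(c15), outpatient_cost = 0)
  ))
  pt <- build_pyramid(panel, 2014); pt1 <- build_pyramid(panel, 2015)
  attrs <- data.frame(
    patient_id = ids,
    sex = rep(c("F", "M"), 6),
    age = c(70, 80, 75, 85, 72, 78, 90, 65, 77, 81, 69, 74),
    frail = c("yes", "no", NA, NA, "yes", "no", "yes", "no", "yes", NA, "no", "yes"),
    stringsAsFactors = FALSE
  )
  cmp <- compare_groups(panel, pt, pt1, attrs)
  # hand tally: M14={h01..h06}, B14={h07..h12}; M15={h01,h02,h05,h06,h07,h08}
  # so h07,h08 move up, h03,h04 move down, the other 8 stay
  expect_equal(unname(c(cmp$groups[["up"]], cmp$groups[["stay"]],
                        cmp$groups[["down"]])), c(2L, 8L, 2L))
  expect_equal(cmp$n, 12L)
  expect_equal(cmp$attributes$frail$n_known, 9L)  # NAs excluded per attribute
  expect_equal(cmp$attributes$sex$n_known, 12L)
  expect_equal(cmp$attributes$age$type, "numeric")
  expect_equal(sum(cmp$attributes$sex$table), 12L)
})

test_that("attributes independent of movement rarely reject; determined ones always do", {
  cfg <- default_config(5000, seed = 23)
  panel <- generate_panel(cfg)
  attrs <- generate_demographics(cfg)
  pt <- build_pyramid(panel, 2014); pt1 <- build_pyramid(panel, 2015)
  cmp <- compare_groups(panel, pt, pt1, attrs)
  ps <- vapply(cmp$attributes, `[[`, 0, "p_value")
  expect_gte(mean(ps > 0.05), 0.9)

  # attribute perfectly determined by movement group -> p ~ 0
  grp <- costpyramid:::movement_groups(pt, pt1)
  det <- data.frame(patient_id = names(grp), marker = as.character(grp),
                    stringsAsFactors = FALSE)
  cmp2 <- compare_groups(panel, pt, pt1, det)
  expect_lt(cmp2$attributes$marker$p_value, 1e-10)
})
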