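# fixtures built in code: tiny hand panels and random panels under a seed

make_panel <- function(...) {
  cost_panel(data.frame(..., stringsAsFactors = FALSE))
}

# a 3-patient, 2-year panel with known costs
tiny_panel <- function() {
  make_panel(
    patient_id = c("p1", "p1", "p2", "p2", "p3"),
    fiscal_year = c(2011L, 2012L, 2011L, 2012L, 2011L),
    inpatient_cost = c(100, 0, 10, 5, 0),
    outpatient_cost = c(50, 0, 0, 5, 0)
  )
}

# random panel: n patients, all utilizing, over the given years
random_panel <- function(n, years = 2011:2012, seed = 42) {
  set.seed(seed)
  df <- expand.grid(patient_id = sprintf("p%03d", seq_len(n)),
                    fiscal_year = years, stringsAsFactors = FALSE)
  df$inpatient_cost <- round(stats::rlnorm(nrow(df), 7, 1.2), 2)
  df$outpatient_cost <- round(stats::rlnorm(nrow(df), 6, 1), 2)
  cost_panel(df)
}

# the study's printed transition matrix and nominal shares
paper_matrix <- function() {
  as_transition_matrix(rbind(
    c(0.24, 0.54, 0.22),
    c(0.05, 0.55, 0.40),
    c(0.02, 0.29, 0.69)
  ), provenance = "printed")
}

nominal_shares <- c(T = 0.05, M = 0.45, B = 0.50)

# build a pyramid directly from a patient_id -> cost vector for one year
pyramid_of <- function(costs, year = 2014L) {
  build_pyramid(make_panel(
    patient_id = names(costs), fiscal_year = year,
    inpatient_cost = unname(costs), outpatient_cost = 0
  ), year)
}
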