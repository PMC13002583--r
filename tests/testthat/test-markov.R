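test_that("transition rows compose competing risks in the documented order", {
  p <- default_parameters()
  M <- build_transition_matrix("universal", p)
  # NSBB row: other-cause death first, bleed among survivors, bleed-death split
  expect_equal(M["HRV_NSBB", "HRV_NSBB"], (1 - 0.034) * (1 - 0.068))
  expect_equal(M["HRV_NSBB", "POST_BLEED"], (1 - 0.034) * 0.068 * (1 - 0.022))
  expect_equal(M["HRV_NSBB", "DEAD_BLEED"], (1 - 0.034) * 0.068 * 0.022)
  expect_equal(M["HRV_NSBB", "DEAD_OTHER"], 0.034)
  # all rows stochastic, for every strategy
  for (s in strategies()) {
    Ms <- build_transition_matrix(s, p)
    expect_true(all(abs(rowSums(Ms) - 1) < 1e-12))
    expect_true(all(Ms >= 0 & Ms <= 1))
  }
  # absorbing rows are identity; post-bleed faces only other-cause death
  expect_equal(unname(M["DEAD_OTHER", "DEAD_OTHER"]), 1)
  expect_equal(unname(M["DEAD_BLEED", "DEAD_BLEED"]), 1)
  expect_equal(unname(M["POST_BLEED", "POST_BLEED"]), 1 - 0.034)
  expect_equal(unname(M["POST_BLEED", "DEAD_BLEED"]), 0)  # one-bleed maximum
  # zero event probabilities give the identity matrix
  M0 <- build_transition_matrix("universal", params_no_events())
  expect_equal(M0, diag(nrow(M0)), ignore_attr = TRUE)
  expect_error(build_transition_matrix("universal", p, 0), "cycle_index")
})

test_that("cycle costs follow the procedure schedules", {
  p <- default_parameters()
  occ <- setNames(numeric(length(health_states())), health_states())
  occ["HRV_LIG"] <- 100
  # ligation cycle: annual endoscopy + biennial procedure + expected bleed cost
  exp_bleed <- 100 * (1 - 0.034) * 0.043 * 1934.52
  expect_equal(cycle_cost("universal", p, 3, occ),
               100 * (96.73 + 744.05) + exp_bleed)
  # off-cycle: no ligation procedure
  expect_equal(cycle_cost("universal", p, 2, occ), 100 * 96.73 + exp_bleed)
  # endoscopy-negative follow-up pays endoscopy at cycles 3 and 5 only
  occ2 <- 0 * occ; occ2["NO_HRV_ENDO"] <- 800
  expect_equal(cycle_cost("universal", p, 2, occ2), 0)
  expect_equal(cycle_cost("universal", p, 3, occ2), 800 * 96.73)
  # surveillance and missed HRV pay the annual non-invasive panel
  occ3 <- 0 * occ; occ3["NO_HRV_SURV"] <- 256; occ3["HRV_MISSED"] <- 6
  expect_equal(cycle_cost("selective", p, 2, occ3),
               262 * (18.60 + 2.68) + 6 * (1 - 0.034) * 0.10 * 1934.52)
  # the dead cost nothing
  occ4 <- 0 * occ; occ4["DEAD_OTHER"] <- 1000
  expect_equal(cycle_cost("universal", p, 3, occ4), 0)
  expect_error(cycle_cost("universal", p, 1, occ - 1), "negative")
})

test_that("cycle QALYs are linear state-utility sums", {
  p <- default_parameters()
  occ <- setNames(numeric(length(health_states())), health_states())
  occ["NO_HRV_SURV"] <- 1000
  expect_equal(cycle_qaly(p, occ), 760)
  occ_dead <- 0 * occ; occ_dead["DEAD_BLEED"] <- 500; occ_dead["DEAD_OTHER"] <- 500
  expect_equal(cycle_qaly(p, occ_dead), 0)
  set.seed(1)
  a <- setNames(runif(length(occ), 0, 50), names(occ))
  b <- setNames(runif(length(occ), 0, 50), names(occ))
  expect_equal(cycle_qaly(p, a + b), cycle_qaly(p, a) + cycle_qaly(p, b))
})

test_that("cohort mass is conserved and dead mass is nondecreasing", {
  for (s in strategies()) {
    tr <- run_cohort(s, default_parameters())
    expect_true(all(abs(rowSums(tr$occupancy) - 1000) < 1e-9))
    dead <- rowSums(tr$occupancy[, dead_states()])
    expect_true(all(diff(dead) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-12))
  }
})

test_that("zero-probability limit reproduces the discounted annuity closed form", {
  # everyone endoscopy-negative at utility 0.76, no events, no costs:
  # QALYs = u * sum_{t=1..5} (1.035)^-(t-1)  (first cycle undiscounted)
  p <- params_zero_costs(params_no_events(params_with("accuracy.prevalence_hrv" = 1e-12)))
  tr <- run_cohort("universal", p)
  expect_equal(tr$qaly_per_capita, 0.76 * annuity(5, 0.035), tolerance = 1e-9)
  expect_equal(tr$cost_per_capita, 0)
  expect_equal(unname(tr$tally["bleeds"]), 0)
})

test_that("discounting is monotone: higher rates never increase totals", {
  rates <- c(0, 0.035, 0.10)
  runs <- lapply(rates, function(r) {
    run_cohort("selective", params_with("econ.discount_rate" = r))
  })
  costs <- vapply(runs, function(x) x$cost_per_capita, numeric(1))
  qalys <- vapply(runs, function(x) x$qaly_per_capita, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("one-bleed maximum holds and bleeds never exceed the cohort", {
  p <- params_with("transitions.p_bleed_missed_hrv" = 1,
                   "transitions.p_bleed_nsbb" = 1,
                   "transitions.p_bleed_ligation" = 1)
  tr <- run_cohort("selective", p)
  expect_lte(unname(tr$tally["bleeds"]), 1000)
  expect_lte(unname(tr$tally["deaths_bleed"]), unname(tr$tally["bleeds"]))
})

test_that("missed-HRV detection pathway moves patients into prophylaxis", {
  p <- params_with()
  p$structure$detect_missed_next_cycle <- TRUE
  p <- validate_parameters(p)
  M <- build_transition_matrix("selective", p)
  stay <- (1 - 0.034) * (1 - 0.10)
  expect_equal(M["HRV_MISSED", "HRV_NSBB"], stay * 0.97 * 0.8)
  expect_equal(M["HRV_MISSED", "HRV_LIG"], stay * 0.97 * 0.2)
  expect_equal(M["HRV_MISSED", "HRV_MISSED"], stay * (1 - 0.97))
  tr <- run_cohort("selective", p)
  tr0 <- run_cohort("selective", default_parameters())
  # detection drains the missed state and adds diagnostic endoscopies
  expect_lt(tr$occupancy["5", "HRV_MISSED"], tr0$occupancy["5", "HRV_MISSED"])
  expect_gt(unname(tr$tally["endoscopies"]), unname(tr0$tally["endoscopies"]))
})

test_that("trace export has one row per cycle-state pair", {
  tr <- run_cohort("universal", default_parameters())
  df <- trace_table(tr)
  expect_equal(nrow(df), 5 * length(health_states()))
  expect_equal(sum(df$occupancy), 5 * 1000, tolerance = 1e-6)
})
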