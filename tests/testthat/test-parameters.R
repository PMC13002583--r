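test_that("classification probabilities match the Bayesian identities", {
  cls <- derive_classification(list(prevalence_hrv = 0.20, sensitivity = 0.97,
                                    specificity = 0.32))
  expect_equal(cls$p_meet, 0.262, tolerance = 1e-12)
  expect_equal(cls$npv, 0.256 / 0.262, tolerance = 1e-12)
  expect_equal(cls$ppv, 0.194 / 0.738, tolerance = 1e-12)
  # rounded to reporting precision
  expect_equal(round(cls$p_meet, 2), 0.26)
  expect_equal(round(cls$npv, 2), 0.98)
  expect_equal(round(cls$ppv, 2), 0.26)

  perfect <- derive_classification(list(prevalence_hrv = 0.20, sensitivity = 1,
                                        specificity = 1))
  expect_equal(perfect$p_meet, 0.80)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$ppv, 1)

  # degenerate triage (nobody meets the criteria) is a configuration error
  expect_error(derive_classification(list(prevalence_hrv = 0.2, sensitivity = 1,
                                          specificity = 0)),
               "degenerate")
  expect_error(derive_classification(list(prevalence_hrv = 0.2, sensitivity = 1.2,
                                          specificity = 0.3)),
               "\\[0, 1\\]")
})

test_that("classification agrees with exhaustive 2x2 contingency enumeration", {
  cases <- list(c(0.30, 0.95, 0.26), c(0.20, 0.97, 0.32), c(0.10, 0.90, 0.50))
  for (cs in cases) {
    oracle <- enumerate_classification(cs[1], cs[2], cs[3])
    cls <- derive_classification(list(prevalence_hrv = cs[1], sensitivity = cs[2],
                                      specificity = cs[3]))
    expect_equal(cls$p_meet, oracle$p_meet, tolerance = 1e-12)
    expect_equal(cls$npv, oracle$npv, tolerance = 1e-12)
    expect_equal(cls$ppv, oracle$ppv, tolerance = 1e-12)
  }
})

test_that("classification satisfies the law of total probability", {
  set.seed(42)
  for (i in 1:200) {
    acc <- list(prevalence_hrv = runif(1, 0.01, 0.99),
                sensitivity = runif(1), specificity = runif(1, 0.01, 0.99))
    p_meet_raw <- acc$prevalence_hrv * (1 - acc$sensitivity) +
      (1 - acc$prevalence_hrv) * acc$specificity
    if (p_meet_raw <= 0 || p_meet_raw >= 1) next
    cls <- derive_classification(acc)
    # P(no HRV) decomposed over the triage outcome
    expect_equal(cls$p_meet * cls$npv + (1 - cls$p_meet) * (1 - cls$ppv),
                 1 - acc$prevalence_hrv, tolerance = 1e-12)
  }
})

test_that("config round-trips losslessly and rejects bad input", {
  p <- params_with("costs.endoscopy" = 120, "accuracy.prevalence_hrv" = 0.25,
                   "econ.discount_rate" = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  serialize_parameters(p, path)
  p2 <- load_parameters(path)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)

  # empty config -> full defaults
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(unclass(load_parameters(empty)), unclass(default_parameters()))
  expect_equal(unclass(load_parameters(NULL)), unclass(default_parameters()))

  # single override leaves everything else at default
  one <- withr::local_tempfile(fileext = ".yaml")
  writeLines("costs.endoscopy: 44.64", one)
  p3 <- load_parameters(one)
  expect_equal(p3$costs$endoscopy, 44.64)
  p3$costs$endoscopy <- default_parameters()$costs$endoscopy
  expect_equal(unclass(p3), unclass(default_parameters()))

  # unknown keys and out-of-range values are errors naming the offender
  bad1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("costs.endoscopy_fee: 10", bad1)
  expect_error(load_parameters(bad1), "unknown config key.*endoscopy_fee")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("transitions.p_bleed_nsbb: 1.5", bad2)
  expect_error(load_parameters(bad2), "p_bleed_nsbb.*out of range")
})

test_that("parameter paths enforce the treatment split and derived-quantity rules", {
  p <- set_parameter(default_parameters(), "transitions.p_nsbb_treatment", 0.7)
  expect_equal(p$transitions$p_ligation_treatment, 0.3)
  expect_error(set_parameter(default_parameters(), "p_meet", 0.3), "derived")
  expect_error(set_parameter(default_parameters(), "accuracy.npv", 0.9), "derived")
  expect_error(get_parameter(default_parameters(), "costs.nope"), "unknown")
  expect_error(validate_parameters(params_with()$accuracy), "group missing")
})

test_that("DSA ranges use printed intervals verbatim and the +/-20% fallback", {
  rng <- default_dsa_ranges()
  row <- function(path) rng[rng$path == path, ]
  expect_equal(row("costs.endoscopy")[, c("low", "high")],
               data.frame(low = 44.64, high = 178.57),
               ignore_attr = TRUE)
  expect_equal(row("accuracy.prevalence_hrv")[, c("low", "high")],
               data.frame(low = 0.10, high = 0.30), ignore_attr = TRUE)
  # uninformative printed 0-1 ranges fall back to +/-20%
  expect_equal(row("transitions.p_death_other")$low, 0.8 * 0.034)
  expect_equal(row("transitions.p_death_other")$high, 1.2 * 0.034)
  expect_equal(row("utilities.u_hrv_untreated")$low, 0.8 * 0.72)
  # derived quantities are not swept directly
  expect_false(any(grepl("p_meet|npv|ppv", rng$path)))
})
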