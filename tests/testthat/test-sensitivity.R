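test_that("a zero-width sweep reproduces the base case at every point", {
  base <- base_case(default_parameters())
  sw <- one_way_sweep(list(path = "costs.endoscopy", low = 96.73, high = 96.73,
                           n_points = 4))
  expect_equal(nrow(sw), 4)
  expect_equal(sw$cost_universal, rep(base$reference[["cost"]], 4))
  expect_equal(sw$inmb,
               rep(unname(base$nmb["comparator"] - base$nmb["reference"]), 4))
})

test_that("the ICER falls strictly as endoscopy gets more expensive", {
  # the selective arm avoids endoscopies, so its relative cost falls as the
  # unit price rises; with fixed positive incremental QALYs the ratio is
  # strictly decreasing (passing through the cost-parity point)
  sw <- one_way_sweep(list(path = "costs.endoscopy", low = 44.64, high = 178.57,
                           n_points = 12))
  expect_true(all(diff(sw$incremental_cost) < 0))
  expect_true(all(abs(diff(sw$incremental_qaly)) < 1e-12))
  expect_true(all(diff(sw$icer) < 0))
  expect_true(all(diff(sw$inmb) > 0))
})

test_that("sweeping a parent parameter equals an independent full re-run", {
  sw <- one_way_sweep(list(path = "accuracy.prevalence_hrv", low = 0.30,
                           high = 0.30, n_points = 1))
  direct <- base_case(params_with("accuracy.prevalence_hrv" = 0.30))
  expect_equal(sw$cost_selective, unname(direct$comparator["cost"]))
  expect_equal(sw$qaly_selective, unname(direct$comparator["qaly"]))
  expect_equal(sw$icer, direct$icer)
  # derived quantities cannot be swept directly
  expect_error(one_way_sweep(list(path = "accuracy.npv", low = 0.9, high = 0.99)),
               "derived")
  expect_error(one_way_sweep(list(path = "costs.endoscopy", low = 10, high = 5)),
               "low must be <= high")
})

test_that("tornado spans decompose into endpoint sweeps and rank by span", {
  specs <- data.frame(path = c("costs.endoscopy", "accuracy.prevalence_hrv",
                               "utilities.u_post_bleed"),
                      low = c(44.64, 0.10, 0.54),
                      high = c(178.57, 0.30, 0.54))
  tor <- tornado(specs = specs)
  expect_equal(nrow(tor), 3)
  # zero-width range has zero span and ranks last
  expect_equal(tor$path[3], "utilities.u_post_bleed")
  expect_equal(tor$abs_span[3], 0)
  # endpoint values reproducible from one_way_sweep calls
  for (i in 1:2) {
    lo <- one_way_sweep(list(path = tor$path[i], low = tor$low[i],
                             high = tor$low[i], n_points = 1))
    hi <- one_way_sweep(list(path = tor$path[i], low = tor$high[i],
                             high = tor$high[i], n_points = 1))
    expect_equal(tor$inmb_at_low[i], lo$inmb)
    expect_equal(tor$inmb_at_high[i], hi$inmb)
  }
  expect_true(all(diff(tor$abs_span) <= 0))
  expect_error(tornado(specs = specs[0, ]), "nonempty")
})

test_that("bisection finds known roots and is bracket-invariant", {
  # linear toy criterion with an analytic root at endoscopy cost 123.4
  toy <- function(p) get_parameter(p, "costs.endoscopy") - 123.4
  t1 <- threshold_search("costs.endoscopy", toy, c(50, 200))
  expect_equal(t1$threshold_value, 123.4, tolerance = 0.01)
  t2 <- threshold_search("costs.endoscopy", toy, c(100, 150))
  expect_equal(t1$threshold_value, t2$threshold_value, tolerance = 0.02)
  expect_error(threshold_search("costs.endoscopy", toy, c(200, 300)),
               "monotone over bracket")
  expect_error(threshold_search("costs.endoscopy", toy, c(300, 200)), "bracket")
  expect_error(threshold_search("costs.endoscopy", "no_such", c(1, 2)),
               "unknown criterion")
})

test_that("the cost-parity threshold matches a direct parity computation", {
  thr <- threshold_search("costs.endoscopy", "cost_parity", c(10, 400))
  at <- function(v) {
    res <- base_case(set_parameter(default_parameters(), "costs.endoscopy", v))
    res$incremental_cost
  }
  expect_lt(abs(at(thr$threshold_value)), 0.05)
  # parity flips: below the threshold universal is cheaper, above it selective
  expect_gt(at(thr$threshold_value - 5), 0)
  expect_lt(at(thr$threshold_value + 5), 0)
})

test_that("two-way accuracy grid flags cost-effectiveness monotonically in specificity", {
  g <- two_way_grid(grid_a = c(0.90, 0.97), grid_b = seq(0.10, 0.50, by = 0.1))
  expect_equal(dim(g$cost_effective), c(2, 5))
  # the base-case cell is cost-effective
  g0 <- two_way_grid(grid_a = 0.97, grid_b = 0.32)
  expect_true(g0$cost_effective[1, 1])
  # more specificity spares more true negatives: NMB nondecreasing along rows
  expect_true(all(apply(g$inmb, 1, function(r) all(diff(r) > -1e-9))))
  # sampled cell equals a direct re-run
  direct <- base_case(params_with("accuracy.sensitivity" = 0.90,
                                  "accuracy.specificity" = 0.30))
  expect_equal(g$inmb[1, 3],
               unname(direct$nmb["comparator"] - direct$nmb["reference"]))
})
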