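test_that("method-of-moments fits reproduce the stated mean and SD", {
  g <- fit_distribution("gamma", 96.73, 44.64, 178.57)
  expect_equal(g$sd, (178.57 - 44.64) / (2 * 1.96), tolerance = 1e-12)
  expect_equal(g$sd, 34.16582, tolerance = 1e-5)
  expect_equal(g$pars$shape * g$pars$scale, 96.73, tolerance = 1e-9)
  expect_equal(sqrt(g$pars$shape) * g$pars$scale, g$sd, tolerance = 1e-9)

  b <- fit_distribution("beta", 0.76, 0.52, 0.95)
  m <- with(b$pars, shape1 / (shape1 + shape2))
  expect_equal(m, 0.76, tolerance = 1e-9)
  v <- with(b$pars, shape1 * shape2 / ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_equal(sqrt(v), b$sd, tolerance = 1e-9)

  tri <- fit_distribution("triangular", 0.5, 0.2, 0.9)
  expect_equal(with(tri$pars, (low + mode + high) / 3), 0.5, tolerance = 1e-12)

  # degenerate range -> point mass, sampling returns the mean
  pt <- fit_distribution("beta", 0.8, 0.8, 0.8)
  expect_equal(pt$family, "point")
  expect_equal(sample_distribution(pt, 5), rep(0.8, 5))

  # infeasible fits fail loudly
  expect_error(fit_distribution("beta", 0.034, 0, 1), "range too wide for beta")
  expect_error(fit_distribution("triangular", 0.034, 0, 1), "mode .* outside")
  expect_error(fit_distribution("gamma", 10, 20, 30), "low <= mean <= high")
})

test_that("the default distribution set covers every DSA parameter", {
  d <- psa_distributions()
  rng <- default_dsa_ranges()
  expect_setequal(names(d), rng$path)
  fams <- vapply(d, function(x) x$family, character(1))
  expect_true(all(fams[startsWith(names(d), "costs.")] == "gamma"))
  expect_true(all(fams[startsWith(names(d), "utilities.")] == "beta"))
})

test_that("joint draws are reproducible, in-domain and mean-consistent", {
  d <- psa_distributions()
  set.seed(99); p1 <- sample_parameter_set(d)
  set.seed(99); p2 <- sample_parameter_set(d)
  expect_identical(p1, p2)
  expect_s3_class(p1, "model_parameters")
  # treatment split renormalized after drawing
  expect_equal(p1$transitions$p_nsbb_treatment +
                 p1$transitions$p_ligation_treatment, 1)
  # law of large numbers: the sample mean of a drawn cost approaches its mean
  set.seed(5)
  x <- sample_distribution(d[["costs.endoscopy"]], 10000)
  expect_lt(abs(mean(x) - 96.73), 3 * sd(x) / sqrt(10000))
  expect_true(all(x > 0))
})

test_that("degenerate distributions collapse the PSA to the base case", {
  rng <- default_dsa_ranges()
  degenerate <- lapply(seq_len(nrow(rng)), function(i) {
    fit_distribution(rng$psa_family[i], rng$base[i], rng$base[i], rng$base[i])
  })
  names(degenerate) <- rng$path
  psa <- run_psa(n_iter = 2, seed = 3, distributions = degenerate)
  base <- base_case(default_parameters())
  expect_equal(psa$draws$dcost, rep(base$incremental_cost, 2), tolerance = 1e-9)
  expect_equal(psa$draws$dqaly, rep(base$incremental_qaly, 2), tolerance = 1e-9)
  expect_true(psa$p_ce_at_wtp %in% c(0, 1))
})

test_that("PSA output is seed-deterministic and its CEAC is coherent", {
  a <- run_psa(n_iter = 40, seed = 17)
  b <- run_psa(n_iter = 40, seed = 17)
  expect_identical(a, b)
  expect_equal(nrow(a$draws), 40)
  # probabilities across strategies sum to one at every WTP
  expect_equal(a$ceac$p_universal + a$ceac$p_selective,
               rep(1, nrow(a$ceac)))
  # CEAC at WTP = 0 is the fraction of iterations where selective is cheaper
  expect_equal(a$ceac$p_selective[1], mean(a$draws$dcost < 0))
  # and converges to the fraction where selective is more effective
  expect_equal(mean(a$draws$dqaly * 1e12 - a$draws$dcost > 0),
               mean(a$draws$dqaly > 0))
  expect_true(all(a$ceac$p_selective >= 0 & a$ceac$p_selective <= 1))
})

test_that("CEAC crossover interpolates the 50% crossing", {
  fake <- list(ceac = data.frame(wtp = c(0, 100, 200, 300),
                                 p_selective = c(0.2, 0.4, 0.6, 0.8)))
  expect_equal(ceac_crossover(fake), 150)
  fake$ceac$p_selective <- c(0.6, 0.7, 0.8, 0.9)
  expect_equal(ceac_crossover(fake), 0)
  fake$ceac$p_selective <- c(0.1, 0.2, 0.3, 0.4)
  expect_true(is.na(ceac_crossover(fake)))
})
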