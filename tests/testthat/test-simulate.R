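test_that("distribution parameters are derived from stated percentiles", {
  g <- distribution_from_interval("gaussian", 8.0, 12.0)
  expect_equal(g$mu, 10.0)
  expect_equal(g$sigma, (12 - 8) / (2 * 1.959964))
  expect_equal(g$sigma, 1.020427, tolerance = 1e-6)

  ln <- distribution_from_interval("lognormal", 0.25, 4.0)
  expect_equal(ln$mu, 0.0)
  expect_equal(ln$sigma, log(16) / (2 * 1.959964))

  # derived parameters reproduce the stated percentiles
  expect_equal(qlnorm(c(0.025, 0.975), ln$mu, ln$sigma), c(0.25, 4.0),
               tolerance = 1e-6)
  expect_equal(qnorm(c(0.025, 0.975), g$mu, g$sigma), c(8.0, 12.0),
               tolerance = 1e-6)

  # explicit (mu, sigma) take precedence over an interval
  hb <- distribution_spec("gaussian", p2_5 = 12, p97_5 = 16,
                          mu = 14.0, sigma = 0.98)
  expect_equal(hb$sigma, 0.98)
  expect_equal(hb$p2_5, 14 - 1.959964 * 0.98)

  expect_error(distribution_from_interval("lognormal", -1, 4), "positive")
  expect_error(distribution_from_interval("gaussian", 5, 2), "smaller")
})

test_that("scenario generation is deterministic with exact abnormal counts", {
  sc <- preset_scenario("hemoglobin", abnormal_fraction = 0.2,
                        cycles = 3, seed = 9, n_total = 500)
  expect_equal(sc$n_abnormal, 100L)
  d1 <- generate_dataset(sc, cycle = 2)
  d2 <- generate_dataset(sc, cycle = 2)
  expect_identical(d1$values, d2$values)
  expect_equal(d1$n, 500L)
  d3 <- generate_dataset(sc, cycle = 3)
  expect_false(identical(d1$values, d3$values))
  expect_error(generate_dataset(sc, cycle = 4), "cycles")
})

test_that("generated physiological samples match the specified moments", {
  sc <- preset_scenario("hemoglobin", cycles = 1, seed = 13)
  d <- generate_dataset(sc, 1)
  expect_equal(d$n, 10000L)
  se <- 0.98 / sqrt(10000)
  expect_lt(abs(mean(d$values) - 14.0), 4 * se)
  expect_lt(abs(sd(d$values) / 0.98 - 1), 0.05)
  # sample 2.5th percentile near the analytic quantile 14 - 1.959964*0.98
  expect_equal(unname(quantile(d$values, 0.025)), 12.079, tolerance = 0.05)

  # log-normal analyte, log-scale moments
  sc2 <- preset_scenario("tsh", cycles = 1, seed = 13, n_total = 20000)
  d2 <- generate_dataset(sc2, 1)
  expect_lt(abs(mean(log(d2$values)) - 0), 4 * 0.707306 / sqrt(20000))
  expect_lt(abs(sd(log(d2$values)) / 0.707306 - 1), 0.05)
})

test_that("nonpositive draws are resampled, not clipped", {
  # abnormal Gaussian centered near zero: naive draws would often be <= 0
  abn <- distribution_spec("gaussian", mu = 0.4, sigma = 0.3)
  sc <- scenario_spec(distribution_spec("gaussian", mu = 10, sigma = 1),
                      abnormal = abn, abnormal_fraction = 0.3,
                      n_total = 1000L, cycles = 1, seed = 2, decimals = 2)
  d <- generate_dataset(sc, 1)
  expect_true(all(d$values > 0))
  expect_equal(d$n, 1000L)

  # essentially all mass nonpositive -> resampling cap error
  hopeless <- distribution_spec("gaussian", mu = -50, sigma = 0.1)
  sc2 <- scenario_spec(distribution_spec("gaussian", mu = 10, sigma = 1),
                       abnormal = hopeless, abnormal_fraction = 0.1,
                       n_total = 100L, cycles = 1, seed = 2)
  expect_error(generate_dataset(sc2, 1), "resampling cap")
})

test_that("run_scenario aggregates per-cycle estimates", {
  sc <- preset_scenario("hemoglobin", cycles = 4, seed = 31, n_total = 1500)
  s <- run_scenario(sc, fast_config(),
                    margins = list(lower = c(11.8, 12.2),
                                   upper = c(15.8, 16.2)))
  expect_equal(nrow(s$estimates), 4)
  expect_lt(abs(s$median_lower - 12.0), 0.5)
  expect_lt(abs(s$median_upper - 16.0), 0.5)
  expect_gte(s$median_lower, s$lower_ci90[1])
  expect_lte(s$median_lower, s$lower_ci90[2])
  expect_true(s$within_margin_lower >= 0 && s$within_margin_lower <= 1)

  # a single cycle gives a degenerate summary equal to that estimate
  sc1 <- preset_scenario("hemoglobin", cycles = 1, seed = 31, n_total = 1500)
  s1 <- run_scenario(sc1, fast_config())
  expect_equal(s1$median_lower, s1$estimates$lower[1])
  expect_equal(s1$lower_ci90, rep(s1$estimates$lower[1], 2))
  expect_true(is.na(s1$within_margin_lower))
})

test_that("scenario summaries are reproducible and thread-invariant", {
  sc <- preset_scenario("hemoglobin", cycles = 3, seed = 17, n_total = 1200)
  s1 <- run_scenario(sc, fast_config())
  s2 <- run_scenario(sc, fast_config(), threads = 3)
  expect_identical(s1$estimates, s2$estimates)
  # cycle datasets agree with generate_dataset under the same stream keys
  d2 <- generate_dataset(sc, 2)
  f2 <- estimate_ri(d2, fast_config())
  expect_equal(s1$estimates$lower[2], f2$lower_limit)
})

test_that("scenario specification enforces the studied contamination range", {
  phys <- distribution_spec("gaussian", mu = 14, sigma = 1)
  expect_error(scenario_spec(phys, abnormal_fraction = 0.4), "0, 0.30")
  expect_error(scenario_spec(phys, abnormal_fraction = 0.1), "abnormal")
})
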