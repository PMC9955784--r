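test_that("entropy accumulates linearly in time", {
  expect_equal(accumulate_entropy(119.9, 40), 4796)
  expect_equal(accumulate_entropy(102.4, 25), 2560)
  expect_equal(accumulate_entropy(500, 0), 0)
})

test_that("survival-fraction adjustment divides the healthy rate", {
  expect_equal(disease_adjusted_rate(119.9, 0.95), 126.2, tolerance = 1e-3)
  expect_equal(disease_adjusted_rate(119.9, 0.44), 272.5)
  expect_equal(disease_adjusted_rate(87.3, 1.0), 87.3)
  expect_error(disease_adjusted_rate(119.9, 0), "survival_fraction")
  expect_error(disease_adjusted_rate(119.9, 1.2), "survival_fraction")
})

test_that("autophagy reduction scales the rate down", {
  expect_equal(autophagy_adjusted_rate(100, 0.10), 90)
  expect_equal(autophagy_adjusted_rate(100, 0), 100)
  # a 25% reduction takes the 50-year-old maintenance rate 121 to ~91
  expect_equal(autophagy_adjusted_rate(121, 0.25), 90.75)
  expect_lte(abs(autophagy_adjusted_rate(121, 0.25) - 91), 1)
})

test_that("lifespan projection walks segments to the budget", {
  expect_equal(
    project_lifespan(entropy_ledger(40, 4796, 272.5))$expected_lifespan_rounded,
    64)
  expect_equal(project_lifespan(entropy_ledger(40, 11404, 100))$expected_lifespan,
               40)
  expect_equal(
    project_lifespan(entropy_ledger(50, 4651, 135))$expected_lifespan_rounded,
    100)
  # multi-segment: 10 years at one rate then open-ended at another equals
  # the closed form applied piecewise
  led <- entropy_ledger(40, 4796, rates = c(150, 100),
                        durations = c(10, Inf))
  expect_equal(project_lifespan(led)$expected_lifespan,
               50 + (11404 - 4796 - 1500) / 100)
  expect_error(entropy_ledger(40, 12000, 100), "exceeds")
  expect_error(entropy_ledger(40, 100, c(100, 100), durations = c(10, 20)),
               "open-ended")
})

test_that("single-segment projection equals the closed form", {
  for (rate in c(76.4, 87.2, 98.8, 126.2, 149.9, 272.5)) {
    got <- project_lifespan(entropy_ledger(40, 4796, rate))$expected_lifespan
    expect_equal(got, 40 + (11404 - 4796) / rate)
  }
})

test_that("projection round-trips with accumulation at full precision", {
  for (rate in c(81.1, 102.4, 121, 135)) {
    ls <- project_lifespan(entropy_ledger(25, 2560, rate))
    expect_equal(2560 + accumulate_entropy(rate, ls$remaining_years), 11404)
  }
})

test_that("lifespan is strictly decreasing in any segment rate", {
  base <- project_lifespan(entropy_ledger(40, 4796, c(120, 100),
                                          durations = c(20, Inf)))
  bump1 <- project_lifespan(entropy_ledger(40, 4796, c(130, 100),
                                           durations = c(20, Inf)))
  bump2 <- project_lifespan(entropy_ledger(40, 4796, c(120, 110),
                                           durations = c(20, Inf)))
  expect_lt(bump1$expected_lifespan, base$expected_lifespan)
  expect_lt(bump2$expected_lifespan, base$expected_lifespan)
})

test_that("constant power-style rate inverts to lifespan from birth", {
  expect_equal(round(constant_rate_lifespan(0.46e-5)), 79)
  expect_equal(constant_rate_lifespan(0.92e-5),
               constant_rate_lifespan(0.46e-5) / 2)
  spy <- 365 * 24 * 3600
  expect_equal(constant_rate_lifespan(11404 / spy), 1)
})

test_that("scenario comparison reports years gained", {
  same <- scenario_compare(entropy_ledger(40, 4796, 126.2),
                           entropy_ledger(40, 4796, 126.2))
  expect_equal(same$years_gained, 0)

  cpC <- scenario_compare(entropy_ledger(40, 4796, 272.5),
                          entropy_ledger(40, 4796, 98.8))
  expect_equal(cpC$years_gained_rounded, 43)
  cpB <- scenario_compare(entropy_ledger(40, 4796, 149.9),
                          entropy_ledger(40, 4796, 87.2))
  expect_equal(cpB$years_gained_rounded, 32)

  expect_error(scenario_compare(entropy_ledger(40, 4796, 100),
                                entropy_ledger(41, 4796, 100)),
               "share")
})

test_that("unit survival fraction is the identity through the pipeline", {
  rate <- 119.9
  adj <- disease_adjusted_rate(rate, 1.0)
  expect_identical(adj, rate)
  expect_equal(
    project_lifespan(entropy_ledger(40, 4796, adj))$expected_lifespan,
    project_lifespan(entropy_ledger(40, 4796, rate))$expected_lifespan)
})
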