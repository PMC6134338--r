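test_that("type-I error of the slope test matches its level", {
  res <- simulate_power(
    power_scenario(n = 150, slope = 0, tails = "one", n_reps = 4000),
    seed = 1
  )
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(res$power - 0.05), 4 * se)
})

test_that("analytic Fisher-z approximation matches its closed form and limits", {
  sc <- power_scenario(n = 150, slope = 0.25, tails = "one")
  expect_equal(
    analytic_power(sc),
    pnorm(atanh(0.25) * sqrt(147) - qnorm(0.95)),
    tolerance = 1e-12
  )
  expect_equal(analytic_power(sc), 0.927, tolerance = 0.001)
  # null: power equals alpha
  expect_equal(
    analytic_power(power_scenario(n = 100, slope = 0, tails = "one")),
    0.05,
    tolerance = 1e-10
  )
  # large-n limit
  expect_gt(analytic_power(power_scenario(n = 5000, slope = 0.25, tails = "one")), 0.9999)
  # declined for ascertained designs
  expect_error(
    analytic_power(power_scenario(frac_ascertained = 0.5)),
    "unbiased"
  )
})

test_that("Monte-Carlo power agrees with the analytic value on unbiased designs", {
  for (n in c(80, 150)) {
    res <- simulate_power(
      power_scenario(n = n, slope = 0.25, tails = "one", n_reps = 4000),
      seed = n
    )
    expect_true(res$analytic >= res$ci[1] - 0.01 && res$analytic <= res$ci[2] + 0.01)
  }
})

test_that("power is monotone in n and in |slope|", {
  pow_n <- vapply(c(50, 100, 200, 400), function(n) {
    analytic_power(power_scenario(n = n, slope = 0.25, tails = "one"))
  }, numeric(1))
  expect_true(all(diff(pow_n) > 0))
  pow_s <- vapply(c(0.1, 0.2, 0.3, 0.4), function(s) {
    analytic_power(power_scenario(n = 150, slope = s, tails = "one"))
  }, numeric(1))
  expect_true(all(diff(pow_s) > 0))

  mc <- vapply(c(60, 150, 300), function(n) {
    simulate_power(
      power_scenario(n = n, slope = 0.25, tails = "one", n_reps = 2000),
      seed = 9
    )$power
  }, numeric(1))
  expect_true(all(diff(mc) > 0))
})

test_that("phenotype ascertainment never increases power", {
  base <- simulate_power(
    power_scenario(n = 130, slope = 0.25, tails = "one", n_reps = 5000),
    seed = 21
  )
  asc <- simulate_power(
    power_scenario(
      n = 130, slope = 0.25, tails = "one", n_reps = 5000,
      frac_ascertained = 0.5, ascertainment_shift = 0.9
    ),
    seed = 22
  )
  se <- sqrt(2) * sqrt(0.1 * 0.9 / 5000)
  expect_lt(asc$power, base$power + 3 * se)

  covadj <- simulate_power(
    power_scenario(
      n = 130, slope = 0.25, tails = "one", n_reps = 5000,
      frac_ascertained = 0.5, ascertainment_shift = 0.9,
      covariate_adjusted = TRUE
    ),
    seed = 23
  )
  expect_lt(covadj$power, base$power)
})

test_that("the ascertained subsample has the intended phenotype shift", {
  # one giant replicate, inspected directly through the internals
  sc <- power_scenario(
    n = 20000, slope = 0.25, tails = "one", n_reps = 1,
    frac_ascertained = 0.5, ascertainment_shift = 0.9
  )
  set.seed(31)
  d <- sctassoc:::.draw_xy(sc$n, 1, sc$slope, sc$maf)
  cthr <- sctassoc:::.truncation_threshold(0.9)
  y <- d$y[, 1]
  kept <- y[y < cthr]
  expect_equal(mean(kept), -0.9, tolerance = 0.05)

  expect_error(power_scenario(slope = 1.2), "slope")
})
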