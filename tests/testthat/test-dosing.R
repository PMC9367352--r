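test_that("Avogadro arithmetic reproduces the worked conversions", {
  expect_equal(molecules_from_mass(1.25e-6, 243.217),
               1.25e-6 * 6.022e23 / 243.217)
  expect_equal(molecules_from_mass(1.25e-6, 243.217) / 1e15, 3,
               tolerance = 0.05)  # printed as 3e15
  expect_equal(molecules_from_mass(3.6e-7, 440.5) / 1e14, 5,
               tolerance = 0.05)  # printed as 5e14
  expect_identical(molecules_from_mass(0, 440.5), 0)
  expect_error(molecules_from_mass(-1e-6, 243.217), "non-negative")
})

test_that("per-mg constants give the exact scheduled molecule counts", {
  expect_identical(dose_molecules(bundled_protocol("cyt_high")), 3.0e15)
  expect_identical(dose_molecules(bundled_protocol("ibr_high")), 5.04e14)
  expect_equal(dose_molecules(bundled_protocol("cyt_low")), 5.76e12)
  expect_equal(dose_molecules(bundled_protocol("ibr_low")), 2.52e14)
  # linear in dose and in mouse mass
  pr <- bundled_protocol("cyt_high")
  pr2 <- treatment_protocol("x", pr$drug, 2 * pr$dose_mg_per_kg,
                            pr$dosing_days)
  pr3 <- treatment_protocol("x", pr$drug, pr$dose_mg_per_kg,
                            pr$dosing_days, mouse_mass_kg = 0.040)
  expect_equal(dose_molecules(pr2), 2 * dose_molecules(pr))
  expect_equal(dose_molecules(pr3), 2 * dose_molecules(pr))
})

test_that("half-life to decay rate matches the bundled drug constants", {
  expect_equal(decay_rate_from_half_life(3), 0.231, tolerance = 1e-3)
  expect_equal(decay_rate_from_half_life(6), 0.116, tolerance = 5e-3)
  expect_equal(decay_rate_from_half_life(1), log(2))
  expect_error(decay_rate_from_half_life(0), "positive")
  # round-trip property over a grid of rates
  for (mu in c(0.01, 0.116, 0.231, 1, 5))
    expect_equal(decay_rate_from_half_life(log(2) / mu), mu)
})

test_that("day patterns become daily impulse schedules", {
  expect_equal(build_schedule(bundled_protocol("cyt_high"))$dose_times,
               c(0, 24, 48))
  sc <- build_schedule(bundled_protocol("ibr_low"))
  expect_equal(sc$dose_times, c(0, 24, 48, 72, 96, 168, 192, 216))
  expect_equal(sc$n_doses, 8L)
  empty <- treatment_protocol("none", bundled_drug("Cyt"), 0, integer(0))
  expect_equal(build_schedule(empty)$n_doses, 0L)
  expect_error(treatment_protocol("dup", bundled_drug("Cyt"), 1, c(1, 1, 2)),
               "duplicate")
})

test_that("combining the cytarabine and ibrutinib arms mixes parameters as published", {
  cmb <- combine_drugs(bundled_protocol("cyt_high"), bundled_protocol("ibr_low"))
  expect_equal(cmb$dose_amount, 3.252e15)
  expect_equal(unname(cmb$fractions), c(0.92, 0.08))
  expect_equal(cmb$mu_C, 0.231 * 0.92 + 0.116 * 0.08)  # 0.2218, prints 0.221
  expect_equal(cmb$mu_AC, 0.0161)
  expect_equal(cmb$mu_CA, 0.161)
  expect_equal(cmb$schedule$dose_times, c(0, 24, 48, 72, 96, 168, 192, 216))
  # convexity: mixed decay rate lies between the two single-drug rates
  exact <- combine_drugs(bundled_protocol("cyt_high"),
                         bundled_protocol("ibr_low"), round_fractions = NULL)
  expect_true(exact$mu_C > 0.116 && exact$mu_C < 0.231)
  expect_equal(sum(exact$fractions), 1)
})

test_that("degenerate combinations behave sensibly", {
  zero_b <- treatment_protocol("ibr_zero", bundled_drug("Ibr"), 0,
                               c(1:5, 8:10), mu_AC = 0)
  cmb <- combine_drugs(bundled_protocol("cyt_high"), zero_b)
  expect_equal(cmb$dose_amount, 3.0e15)
  expect_equal(cmb$mu_C, 0.231)
  expect_equal(cmb$mu_AC, 0.012)
  zero_a <- treatment_protocol("cyt_zero", bundled_drug("Cyt"), 0, 1:3,
                               mu_AC = 0)
  expect_error(combine_drugs(zero_a, zero_b), "zero")
})

test_that("protocol YAML configs load to the bundled definitions", {
  for (nm in c("cyt_low", "cyt_high", "ibr_low", "ibr_high")) {
    f <- system.file("extdata", "protocols", paste0(nm, ".yaml"),
                     package = "leukodyn")
    got <- read_protocol(f)
    want <- bundled_protocol(nm)
    expect_equal(got$dosing_days, want$dosing_days, label = nm)
    expect_equal(got$dose_mg_per_kg, want$dose_mg_per_kg, label = nm)
    expect_equal(got$mu_AC, want$mu_AC, label = nm)
    expect_equal(got$drug$mu_C, want$drug$mu_C, label = nm)
  }
  expect_equal(parse_day_pattern("1-5,8-10"), c(1:5, 8:10))
  expect_equal(parse_day_pattern(c(3, 1, 2)), 1:3)
})
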