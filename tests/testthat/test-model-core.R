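test_that("right-hand side matches hand arithmetic at landmark states", {
  p <- model_parameters()
  # extinction state is a fixed point of the smooth flow
  expect_identical(unname(evaluate_rhs(c(0, 0, 0), p)), c(0, 0, 0))
  # logistic term vanishes at carrying capacity (immune-free)
  rhs_K <- evaluate_rhs(c(p$K, 0, 0), p)
  expect_identical(unname(rhs_K[["dA_dt"]]), 0)
  # treatment-start state, term-by-term arithmetic done independently
  A <- 5e4; E <- 2500
  dA <- 0.01 * A * (1 - A / 4e6) - 2e-12 * A * E
  dE <- -4e-5 * E + 4e-14 * A * E / (1e2 + A) - 4e-15 * A * E
  got <- evaluate_rhs(system_state(), p)
  expect_equal(got[["dA_dt"]], dA, tolerance = 1e-12)
  expect_equal(got[["dE_dt"]], dE, tolerance = 1e-12)
  expect_identical(got[["dC_dt"]], 0)
  expect_error(evaluate_rhs(c(-1, 0, 0), p), "'A'")
})

test_that("closed-form logistic behaves at its edge cases", {
  expect_equal(logistic_closed_form(4e6, 0.01, 4e6, c(0, 10, 1e4)),
               rep(4e6, 3))
  expect_equal(logistic_closed_form(5e4, 0.01, 4e6, 0), 5e4)
  tt <- seq(0, 600, by = 50)
  expect_true(all(diff(logistic_closed_form(5e4, 0.01, 4e6, tt)) > 0))
  expect_error(logistic_closed_form(0, 0.01, 4e6, 1), "positive")
})

test_that("drug-free immune-free integration matches the logistic oracle", {
  tr <- simulate_model(logistic_params(), t_end = 600)
  oracle <- logistic_closed_form(5e4, 0.01, 4e6, tr$time_h)
  expect_lt(max(abs(tr$A_cells - oracle) / oracle), 1e-6)
})

test_that("drug decay with no tumor matches the exponential oracle", {
  # A = 0 kills the tumor-dependent clearance term; C decays as d*exp(-mu_C t)
  d <- 3e15
  p <- model_parameters()
  tr <- simulate_model(p, schedule = dose_schedule(d, 0),
                       initial = system_state(A = 0, E = 0, C = 0),
                       t_end = 48)
  post <- tr[-1, ]  # drop the pre-impulse row at t = 0
  oracle <- d * exp(-p$mu_C * post$time_h)
  expect_lt(max(abs(post$C_molecules - oracle) / oracle), 1e-6)
})

test_that("doses are exact jumps in C recorded as pre/post sample pairs", {
  d <- 5.04e14
  sched <- dose_schedule(d, c(0, 24, 48, 72, 96, 168, 192, 216))
  tr <- simulate_model(model_parameters(mu_AC = 0.0042, mu_C = 0.116),
                       sched, t_end = 288)
  for (tm in sched$dose_times) {
    idx <- which(tr$time_h == tm)
    expect_length(idx, 2L)
    expect_equal(tr$C_molecules[idx[2]] - tr$C_molecules[idx[1]], d)
  }
  jumps <- diff(tr$C_molecules)[diff(tr$time_h) == 0]
  expect_equal(sum(jumps), sched$n_doses * d)
  expect_true(all(diff(tr$time_h) >= 0))
})

test_that("states stay non-negative and the tumor stays bounded by K", {
  p <- model_parameters()
  tr <- simulate_model(p, dose_schedule(3e15, c(0, 24, 48)), t_end = 288)
  expect_true(all(tr$A_cells >= 0 & tr$E_cells >= 0 & tr$C_molecules >= 0))
  expect_true(all(tr$A_cells <= p$K * (1 + 1e-6)))
  # drug-free control approaching capacity also stays bounded
  ctl <- simulate_model(logistic_params(), t_end = 1500)
  expect_true(all(ctl$A_cells <= 4e6 * (1 + 1e-6)))
})

test_that("halving the integration tolerances barely moves the endpoint", {
  pr <- bundled_protocol("cyt_high")
  base <- protocol_inhibition(pr)
  tight <- protocol_inhibition(pr, rtol = 5e-11, atol = c(5e-3, 5e-3, 0.5))
  a_base <- 1 - base / 100
  a_tight <- 1 - tight / 100
  expect_lt(abs(a_base - a_tight) / a_tight, 1e-4)
})

test_that("inhibition_percent covers identity, full kill and the error cases", {
  ctl <- simulate_model(logistic_params(), t_end = 48)
  expect_equal(inhibition_percent(ctl, ctl, t_eval = 48), 0)
  dead <- ctl
  dead$A_cells[] <- 0
  expect_equal(inhibition_percent(ctl, dead, t_eval = 48), 100)
  expect_error(inhibition_percent(dead, ctl, t_eval = 48), "undefined")
  expect_error(trajectory_state(ctl, 49), "outside")
})

test_that("integration rejects dose times outside the span", {
  expect_error(
    simulate_model(model_parameters(), dose_schedule(1e15, c(0, 300)),
                   t_end = 288),
    "within")
  expect_error(simulate_model(model_parameters(), t_end = 0), "exceed")
})

test_that("trajectories round-trip through CSV with their JSON sidecar", {
  tr <- simulate_model(model_parameters(), dose_schedule(3e15, c(0, 24)),
                       t_end = 48)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, tmp)
  back <- read_trajectory(tmp)
  expect_equal(back$A_cells, tr$A_cells)
  expect_equal(attr(back, "schedule")$dose_times, c(0, 24))
  expect_equal(unclass(attr(back, "params")),
               unclass(attr(tr, "params")))
})
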