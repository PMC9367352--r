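test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(groups = c("control", "cyt_high"))
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$a20_count, c$a20_count))
})

test_that("cohort table structure matches the study design", {
  cfg <- cohort_config(n_mice = 4)
  coh <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(coh), 5 * 4 * 2)  # five groups, four mice, two bleeds
  expect_true(all(coh$a20_count >= 0 & coh$a20_count <= coh$readout_depth))
  per_mouse <- table(coh$mouse_id, coh$timepoint)
  expect_true(all(per_mouse == 1))
  expect_setequal(unique(coh$day), c(0, 12))
})

test_that("noise-free generation reproduces the model exactly", {
  cfg <- cohort_config(groups = c("control", "cyt_high"),
                       mouse_effect_sd = 0, count_noise = "none")
  coh <- generate_cohort(cfg, seed = 1)
  ctl_pre <- coh$a20_count[coh$group == "control" & coh$timepoint == "pre"][1]
  ctl_post <- coh$a20_count[coh$group == "control" & coh$timepoint == "post"][1]
  p0 <- model_parameters(mu_AC = 0, mu_CA = 0)
  ctl <- simulate_model(p0, t_end = 288)
  expect_equal(ctl_post / ctl_pre,
               trajectory_state(ctl, 288)[["A"]] / 5e4, tolerance = 1e-9)
  # the frequency-based estimator collapses to the trajectory readout
  est <- estimate_inhibition(coh, "cyt_high")
  direct <- protocol_inhibition(bundled_protocol("cyt_high"))
  expect_equal(est, direct, tolerance = 1e-6)
})

test_that("estimator handles the degenerate readouts", {
  cfg <- cohort_config(groups = "control", mouse_effect_sd = 0,
                       count_noise = "none")
  coh <- generate_cohort(cfg, seed = 1)
  # a treated group drawn identically to control shows zero inhibition
  fake <- coh
  fake$group <- "treated"
  fake$mouse_id <- sub("control", "treated", fake$mouse_id)
  both <- rbind(coh, fake)
  expect_equal(estimate_inhibition(both, "treated"), 0)
  # complete kill: all post counts zero
  dead <- both
  dead$a20_count[dead$group == "treated" & dead$timepoint == "post"] <- 0
  expect_equal(estimate_inhibition(dead, "treated"), 100)
  expect_error(estimate_inhibition(fake, "treated"), "no control")
  expect_error(estimate_inhibition(both, "ibr_low"), "not present")
})

test_that("estimator converges to the model inhibition at depth and is
          invariant to the sampling fraction", {
  direct <- protocol_inhibition(bundled_protocol("cyt_high"))
  cfg_deep <- cohort_config(groups = c("control", "cyt_high"),
                            mouse_effect_sd = 0, readout_depth = 2e7)
  est_deep <- estimate_inhibition(generate_cohort(cfg_deep, seed = 9),
                                  "cyt_high")
  expect_equal(est_deep, direct, tolerance = 0.005)
  # sampling fraction is a nuisance constant for the noise-free estimator
  for (sf in c(5e-7, 1e-7)) {
    cfg <- cohort_config(groups = c("control", "cyt_high"),
                         sampling_fraction = sf, mouse_effect_sd = 0,
                         count_noise = "none")
    est <- estimate_inhibition(generate_cohort(cfg, seed = 1), "cyt_high")
    expect_equal(est, direct, tolerance = 1e-6)
  }
})

test_that("noisy group means stay within Monte-Carlo bands of the model", {
  direct <- protocol_inhibition(bundled_protocol("cyt_high"))
  cfg <- cohort_config(groups = c("control", "cyt_high"))
  ests <- vapply(1:30, function(s)
    estimate_inhibition(generate_cohort(cfg, seed = s), "cyt_high"),
    numeric(1))
  expect_lt(abs(mean(ests) - direct), 2)
})

test_that("saturating blood frequencies raise the advisory error", {
  cfg <- cohort_config(groups = "control", sampling_fraction = 1e-2)
  expect_error(generate_cohort(cfg, seed = 1), "sampling_fraction")
})

test_that("cohort CSV round-trips", {
  coh <- generate_cohort(cohort_config(groups = "control"), seed = 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$a20_count, coh$a20_count)
  expect_s3_class(back, "ld_cohort")
})
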