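test_that("baseline generation is reproducible and hits its targets", {
  expect_error(cohort_config(n = 0), "at least 1")
  cfg <- cohort_config(n = 500, seed = 14)
  b1 <- generate_baseline(cfg)
  b2 <- generate_baseline(cfg)
  expect_identical(b1, b2)
  b3 <- generate_baseline(cohort_config(n = 500, seed = 15))
  expect_false(identical(b1, b3))
  expect_true(all(b1$age >= 60))
  expect_true(all(as.matrix(b1[cogmsm:::BIOMARKERS]) > 0))
})

test_that("biomarker medians land near the configured targets", {
  b <- generate_baseline(cohort_config(n = 5000, seed = 16))
  expect_gt(median(b$nfl), 15.6)
  expect_lt(median(b$nfl), 21.0)
  expect_equal(median(b$gfap), 124.4, tolerance = 0.15)
  expect_equal(median(b$age), 72, tolerance = 0.1)
  expect_equal(mean(b$sex), 0.615, tolerance = 0.05)
  # age gradient in NfL mirrors the configured slope
  expect_gt(median(b$nfl[b$age >= 78]), median(b$nfl[b$age < 78]))
})

test_that("an invalid correlation matrix is rejected", {
  R <- matrix(0.9, 6, 6); diag(R) <- 1; R[1, 2] <- R[2, 1] <- -0.9
  expect_error(cohort_config(biomarker_corr = R), "positive semi-definite")
})

test_that("zero intensities freeze the trajectory in its initial state", {
  p <- intensity_params(log_rate = rep(-Inf, 6))
  path <- simulate_trajectory(70, params = p, start_state = "NC",
                              horizon = 90)
  expect_equal(path, data.frame(age = 70, state = "NC"))
})

test_that("constant pure-death simulation matches the exponential mean", {
  p <- pure_death_params(0.1)
  set.seed(17)
  times <- replicate(10000, {
    path <- simulate_trajectory(70, params = p, horizon = 1000)
    path$age[2] - 70
  })
  expect_equal(mean(times), 10, tolerance = 0.03)  # 10 +/- 0.3
})

test_that("thinning reproduces the Gompertz survival function", {
  p <- pure_death_params(0.01, shape = 0.1)
  set.seed(18)
  surv <- mean(replicate(4000, {
    path <- simulate_trajectory(70, params = p, horizon = 75)
    nrow(path) == 1
  }))
  truth <- gompertz_survival(0.01, 0.1, 70, 75)
  expect_lt(abs(surv - truth), 3 * sqrt(truth * (1 - truth) / 4000))
})

test_that("the visit schedule switches from 6- to 3-year spacing at 78", {
  cfg <- cohort_config(n = 1, seed = 1, censor_frac = 0)
  nc_path <- data.frame(age = 72, state = "NC")
  rec <- observe_panel(nc_path, cfg, subject_id = 1, seed = 1)
  expect_equal(rec$ages, c(72, 78, 81, 84, 87))
  expect_true(all(rec$states == 0L))
  cfg25 <- cohort_config(n = 1, seed = 1, censor_frac = 0, max_followup = 24)
  rec2 <- observe_panel(data.frame(age = 62, state = "NC"), cfg25,
                        subject_id = 1, seed = 1)
  expect_equal(rec2$ages, c(62, 68, 74, 80, 83, 86))
})

test_that("deaths are recorded exactly, with the dementia interval flagged", {
  cfg <- cohort_config(n = 1, seed = 1, censor_frac = 0)
  # dementia onset between the last visit and death
  path <- data.frame(age = c(72, 79.5, 80.2), state = c("NC", "DEM", "DEATH"))
  rec <- observe_panel(path, cfg, subject_id = 1, seed = 1)
  expect_equal(rec$states, c(0L, 0L, 4L))
  expect_equal(rec$ages[3], 80.2)
  # dementia observed at a visit, then death
  path2 <- data.frame(age = c(72, 77, 80.2), state = c("NC", "DEM", "DEATH"))
  rec2 <- observe_panel(path2, cfg, subject_id = 1, seed = 1)
  expect_equal(rec2$states, c(0L, 2L, 4L))
  # dementia-free death (visit at 78 precedes it)
  path3 <- data.frame(age = c(72, 80.2), state = c("NC", "DEATH"))
  rec3 <- observe_panel(path3, cfg, subject_id = 1, seed = 1)
  expect_equal(rec3$states, c(0L, 0L, 3L))
  expect_equal(rec3$ages, c(72, 78, 80.2))
  expect_error(observe_panel(path3[0, ], cfg), "empty path")
})

test_that("generated panels always satisfy the record invariants", {
  for (seed in 1:4) {
    cfg <- cohort_config(n = 40, seed = seed,
                         censor_frac = c(0, 0.3)[seed %% 2 + 1],
                         dropout = c("none", "random")[seed %% 2 + 1])
    coh <- generate_cohort(cfg)
    expect_length(coh$panel, 40)
    for (r in coh$panel) {
      expect_true(all(diff(r$ages) > 0))
      dp <- which(r$states %in% 3:4)
      if (length(dp)) expect_equal(dp, length(r$states))
      expect_true(all(r$states %in% c(0:4, 9L)))
    }
  }
})

test_that("stronger true effects yield larger estimated hazard ratios", {
  est <- sapply(c(0, log(2), log(4)), function(b) {
    coh <- small_cohort(n = 350, seed = 23, beta_mci_dem = b)
    fit <- fit_msm(coh$panel, covariates = "nfl_z",
                   beta_transitions = "MCI->DEM", gompertz = FALSE,
                   control = list(hessian = FALSE))
    fit$estimates[["beta:MCI->DEM:nfl_z"]]
  })
  expect_true(all(diff(est) > 0))
})

test_that("noisy emissions still allow accurate staging", {
  cfg <- cohort_config(n = 250, seed = 24, censor_frac = 0)
  coh <- generate_cohort(cfg)
  visits <- emit_cognitive_tests(coh$visit_states, cfg)
  staged <- stage_cohort(visits)
  truth <- coh$visit_states$true_state[
    match(paste(staged$subject_id, staged$visit_age),
          paste(coh$visit_states$subject_id, coh$visit_states$visit_age))]
  expect_gt(mean(staged$state == truth, na.rm = TRUE), 0.8)
  # dementia flags pass through unchanged
  expect_true(all(staged$state[truth == "DEM"] == "DEM"))
})
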