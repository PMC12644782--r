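test_that("constant-hazard MLE equals the occurrence/exposure closed form", {
  # pure-death data with exact death times and right censoring:
  # lambda-hat = deaths / person-years
  set.seed(11)
  death_t <- round(runif(30, 0.5, 9.5), 2)
  recs <- c(
    lapply(seq_along(death_t), function(i)
      panel_record(i, c(70, 70 + death_t[i]), c(0, 3))),
    lapply(31:50, function(i) panel_record(i, c(70, 80), c(0, 0))))
  fit <- fit_msm(panel_data(recs), structure = pure_death_structure(),
                 gompertz = FALSE)
  py <- sum(death_t) + 20 * 10
  expect_equal(exp(fit$estimates[["lograte:NC->DEATH"]]), 30 / py,
               tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$loglik, 30 * log(30 / py) - (30 / py) * py,
               tolerance = 1e-6)
})

test_that("the reported log-likelihood reproduces at the estimates", {
  coh <- small_cohort(n = 150)
  fit <- fit_msm(coh$panel, covariates = "nfl_z",
                 beta_transitions = "MCI->DEM", gompertz = FALSE)
  expect_equal(loglik_total(coh$panel, fit$params), fit$loglik,
               tolerance = 1e-8)
  # refitting from the optimum stays at the same log-likelihood
  refit <- fit_msm(coh$panel, covariates = "nfl_z",
                   beta_transitions = "MCI->DEM", gompertz = FALSE,
                   init = fit$params)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("hazard_ratio applies the Wald formula on the log scale", {
  fake <- structure(list(
    estimates = c("beta:MCI->DEM:x" = 0, "beta:MCI->NC:x" = log(2)),
    vcov = diag(c(0.01, 0.01)) |>
      `dimnames<-`(list(c("beta:MCI->DEM:x", "beta:MCI->NC:x"),
                        c("beta:MCI->DEM:x", "beta:MCI->NC:x")))),
    class = "msm_fit")
  h0 <- hazard_ratio(fake, "MCI->DEM", "x")
  expect_equal(unname(h0[c("hr", "lo95", "hi95")]),
               c(1, 0.82, 1.22), tolerance = 0.005)
  h1 <- hazard_ratio(fake, "MCI->NC", "x")
  expect_equal(unname(h1[c("hr", "lo95", "hi95")]),
               c(2, 1.64, 2.43), tolerance = 0.005)
  expect_error(hazard_ratio(fake, "NC->MCI", "x"), "no such effect")
})

test_that("missing covariance leaves the HR but drops the CI", {
  fake <- structure(list(
    estimates = c("beta:MCI->DEM:x" = log(2)),
    vcov = matrix(NA_real_, 1, 1,
                  dimnames = rep(list("beta:MCI->DEM:x"), 2))),
    class = "msm_fit")
  h <- hazard_ratio(fake, "MCI->DEM", "x")
  expect_equal(h[["hr"]], 2)
  expect_true(is.na(h[["lo95"]]) && is.na(h[["hi95"]]))
})

test_that("hazard ratios are invariant to the reference age", {
  coh <- small_cohort(n = 250, seed = 3)
  f60 <- fit_msm(coh$panel, covariates = "nfl_z",
                 beta_transitions = "MCI->DEM")
  f75 <- fit_msm(coh$panel, covariates = "nfl_z",
                 beta_transitions = "MCI->DEM", ref_age = 75)
  b <- "beta:MCI->DEM:nfl_z"
  expect_equal(f60$estimates[[b]], f75$estimates[[b]], tolerance = 1e-3)
  # shifting the reference age moves the log rates by shape * shift
  expect_equal(f60$estimates[["lograte:NC->MCI"]] +
                 15 * f60$estimates[["shape:NC->MCI"]],
               f75$estimates[["lograte:NC->MCI"]], tolerance = 5e-2)
})

test_that("unit weights reproduce the unweighted fit exactly", {
  coh <- small_cohort(n = 150, seed = 5)
  f1 <- fit_msm(coh$panel, covariates = "nfl_z",
                beta_transitions = "MCI->DEM", gompertz = FALSE)
  f2 <- weighted_refit(coh$panel, rep(1, length(coh$panel)),
                       covariates = "nfl_z",
                       beta_transitions = "MCI->DEM", gompertz = FALSE)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("doubling all weights leaves point estimates unchanged", {
  coh <- small_cohort(n = 150, seed = 5)
  f1 <- fit_msm(coh$panel, covariates = "nfl_z",
                beta_transitions = "MCI->DEM", gompertz = FALSE)
  f2 <- weighted_refit(coh$panel, rep(2, length(coh$panel)),
                       covariates = "nfl_z",
                       beta_transitions = "MCI->DEM", gompertz = FALSE)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  i <- "beta:MCI->DEM:nfl_z"
  expect_equal(f2$vcov[i, i], f1$vcov[i, i] / 2, tolerance = 0.05)
})

test_that("age-dependent fits recover equal effects on both sides", {
  coh <- small_cohort(n = 700, seed = 9)
  fit <- age_dependent_fit(coh$panel, covariates = "nfl_z",
                           beta_transitions = "MCI->DEM", gompertz = FALSE)
  by <- fit$estimates[["beta:MCI->DEM:nfl_z:young"]]
  bo <- fit$estimates[["beta:MCI->DEM:nfl_z:old"]]
  expect_lt(abs(by - bo), 0.6)  # equal true effects, within MC error
  expect_lt(abs(by - log(2)), 0.5)
})

test_that("a threshold below all ages reduces to the single-effect fit", {
  coh <- small_cohort(n = 200, seed = 2)
  single <- fit_msm(coh$panel, covariates = "nfl_z",
                    beta_transitions = "MCI->DEM", gompertz = FALSE)
  expect_message(
    split <- age_dependent_fit(coh$panel, covariates = "nfl_z",
                               threshold_age = 40,
                               beta_transitions = "MCI->DEM",
                               gompertz = FALSE, control = list(hessian = FALSE)),
    "below all")
  expect_equal(split$estimates[["beta:MCI->DEM:nfl_z:old"]],
               single$estimates[["beta:MCI->DEM:nfl_z"]], tolerance = 1e-3)
  # the unexposed young side never moves from its initial value
  expect_equal(split$estimates[["beta:MCI->DEM:nfl_z:young"]], 0,
               tolerance = 1e-8)
})

test_that("count_transitions matches a hand count on a printed fixture", {
  recs <- panel_data(list(
    panel_record(1, c(70, 76, 82), c(0, 0, 1)),   # NC->MCI
    panel_record(2, c(71, 77, 81), c(0, 1, 0)),   # NC->MCI, MCI->NC
    panel_record(3, c(80, 83, 86), c(1, 2, 4)),   # MCI->DEM, death with DEM
    panel_record(4, c(78, 81), c(0, 4)),          # latent MCI->DEM death
    panel_record(5, c(72, 78, 81), c(0, 9, 0))))  # censored, no change
  ct <- count_transitions(recs)
  expect_equal(ct$transitions[["NC->MCI"]], 2L)
  expect_equal(ct$transitions[["MCI->NC"]], 1L)
  expect_equal(ct$transitions[["MCI->DEM"]], 1L)
  expect_equal(ct$transitions[["DEM->DEATH"]], 2L)
  expect_equal(ct$pairs["NC", "DEM"], 1L)  # subject 4 enters DEM latently
  expect_equal(ct$participants[["NC"]], 4L)
  # no state changes anywhere -> all counts zero
  quiet <- panel_data(list(panel_record(1, c(70, 76), c(0, 0))))
  expect_true(all(count_transitions(quiet)$transitions == 0))
})
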