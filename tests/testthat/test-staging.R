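norms1 <- staging_norms(data.frame(
  age_stratum = "70s",
  domain = c("memory", "memory", "speed"),
  test = c("recall", "recognition", "digit"),
  mean = c(10, 20, 30), sd = c(2, 4, 5)))

test_that("domain z-scores standardise and average within domains", {
  sc <- data.frame(domain = c("memory", "memory", "speed"),
                   test = c("recall", "recognition", "digit"),
                   value = c(10, 20, 30))
  z <- compute_domain_zscores(sc, norms1, "70s")
  expect_equal(unname(z[c("memory", "speed")]), c(0, 0))
  sc$value <- c(6, 20, 30)  # recall z = -2, recognition z = 0 -> mean -1
  z <- compute_domain_zscores(sc, norms1, "70s")
  expect_equal(z[["memory"]], -1)
  # exact -1.5 SD boundary input
  sc2 <- data.frame(domain = "speed", test = "digit", value = 30 - 1.5 * 5)
  expect_equal(compute_domain_zscores(sc2, norms1, "70s")[["speed"]], -1.5)
  # missing tests drop out; empty domains are absent
  sc3 <- data.frame(domain = "memory", test = "recall", value = c(10))
  expect_named(compute_domain_zscores(sc3, norms1, "70s"), "memory")
  expect_error(compute_domain_zscores(
    data.frame(domain = "language", test = "fluency", value = 1),
    norms1, "70s"), "missing")
})

test_that("the MCI rule combines cognition, function and diagnosis", {
  z <- c(a = 0.2, b = -1.6, c = 0.5, d = 0, e = 0.1)
  expect_equal(as.character(classify_mci(z, 1, TRUE, FALSE)), "MCI")
  expect_equal(as.character(classify_mci(z - z + 0.5, 0, TRUE, FALSE)), "NC")
  st <- classify_mci(z, 2, TRUE, FALSE)  # functional criterion fails
  expect_equal(as.character(st), "NC")
  expect_true(attr(st, "functional_fail"))
  expect_equal(as.character(classify_mci(z, 0, FALSE, FALSE)), "NC")
  expect_equal(classify_mci(z, 0, TRUE, TRUE), "DEM")
  expect_error(classify_mci(numeric(0), 0, TRUE, FALSE), "censored")
})

test_that("boundary inclusivity: -1.5 triggers impairment, -1.4999 does not", {
  expect_equal(as.character(classify_mci(c(m = -1.5), 0, TRUE, FALSE)), "MCI")
  expect_equal(as.character(classify_mci(c(m = -1.4999), 0, TRUE, FALSE)), "NC")
  expect_equal(classify_cind(c(m = -1.5), FALSE), "MCI")
  expect_equal(classify_cind(c(m = -1.4999), FALSE), "NC")
})

test_that("staging is exhaustively correct on the rule grid and CIND covers MCI", {
  grid <- expand.grid(z = c(-1.6, -1.5, -1.4), iadl = 0:2,
                      adl = c(TRUE, FALSE), dem = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    want <- if (g$dem) "DEM"
      else if (g$z <= -1.5 && g$iadl <= 1 && g$adl) "MCI" else "NC"
    got <- classify_mci(c(d1 = g$z), g$iadl, g$adl, g$dem)
    expect_equal(as.character(got), want)
    cind <- classify_cind(c(d1 = g$z), g$dem)
    if (as.character(got) == "MCI") expect_equal(cind, "MCI")  # superset
    if (g$dem) expect_equal(cind, "DEM")
  }
})

test_that("staging is invariant to a common shift of means and raw scores", {
  sc <- data.frame(domain = c("memory", "speed"), test = c("recall", "digit"),
                   value = c(6.9, 30))
  shifted <- norms1
  shifted$mean <- shifted$mean + 100
  sc2 <- sc; sc2$value <- sc2$value + 100
  z1 <- compute_domain_zscores(sc, norms1, "70s")
  z2 <- compute_domain_zscores(sc2, shifted, "70s")
  expect_equal(z1, z2)
})

test_that("stage_cohort recovers true states from noiseless emissions", {
  beta <- NULL
  cfg <- cohort_config(n = 60, seed = 21, censor_frac = 0,
                       emission = list(mci_shift = -2, dem_shift = -3,
                                       noise_sd = 1e-6, p_iadl1_nc = 0,
                                       p_iadl1_mci = 0, fn_error = 0))
  coh <- generate_cohort(cfg)
  visits <- emit_cognitive_tests(coh$visit_states, cfg)
  # norms from a pure-NC reference so that state means are exactly 0
  norms <- staging_norms(expand.grid(
    age_stratum = unique(visits$age_stratum),
    domain = unique(visits$domain), test = unique(visits$test),
    stringsAsFactors = FALSE) |> transform(mean = 0, sd = 1))
  # keep valid (domain, test) combinations only
  norms <- norms[paste(norms$domain, norms$test) %in%
                   unique(paste(visits$domain, visits$test)), ]
  staged <- stage_cohort(visits, norms = norms)
  truth <- coh$visit_states$true_state[
    match(paste(staged$subject_id, staged$visit_age),
          paste(coh$visit_states$subject_id, coh$visit_states$visit_age))]
  expect_equal(staged$state, truth)
})
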