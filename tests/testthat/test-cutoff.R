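test_that("train/test splits are exhaustive, disjoint and seed-reproducible", {
  s <- split_train_test(1:10, 0.8, seed = 4)
  expect_length(s$train, 8)
  expect_length(s$test, 2)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_identical(split_train_test(1:10, 0.8, seed = 4), s)
  # different seeds give different splits with overwhelming probability
  splits <- sapply(1:5, function(sd)
    paste(sort(split_train_test(1:100, 0.8, seed = sd)$train), collapse = ","))
  expect_gt(length(unique(splits)), 1)
  expect_error(split_train_test(1, 0.8), "at least two")
  expect_error(split_train_test(1:10, 1.2), "fraction")
})

test_that("the Youden sweep finds the separating midpoint", {
  v <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  out <- youden_optimal_cutoff(v, y, "high")
  expect_equal(out$threshold, 6.5)
  expect_equal(out$J, 1)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
})

test_that("identical class distributions give J = 0", {
  v <- rep(c(1, 2, 3), 2)
  y <- rep(c(0, 1), each = 3)
  out <- youden_optimal_cutoff(v, y, "high")
  expect_equal(out$J, 0, tolerance = 1e-12)
  expect_error(youden_optimal_cutoff(1:5, rep(1, 5)), "classes")
})

test_that("the sweep attains the analytic optimum for equal-variance normals", {
  set.seed(42)
  v <- c(rnorm(5000, 0), rnorm(5000, 2))
  y <- rep(c(0, 1), each = 5000)
  out <- youden_optimal_cutoff(v, y, "high")
  expect_lt(abs(out$threshold - 1), 0.1)
  # the reported maximum matches an exhaustive evaluation over candidates
  u <- sort(unique(v))
  cand <- (u[-1] + u[-length(u)]) / 2
  Jall <- sapply(cand, function(th)
    mean(v[y == 1] > th) + mean(v[y == 0] <= th) - 1)
  expect_equal(out$J, max(Jall), tolerance = 1e-12)
  expect_true(out$J >= -1 && out$J <= 1)
})

test_that("low-direction sweeps mirror high-direction ones", {
  v <- c(1, 2, 3, 10, 11, 12)
  out <- youden_optimal_cutoff(v, c(1, 1, 1, 0, 0, 0), "low")
  expect_equal(out$threshold, 6.5)
  expect_equal(out$J, 1)
})

test_that("bootstrap cut-offs stay in the separating gap and concentrate", {
  v <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  bs <- bootstrap_cutoff(v, y, "high", n_boot = 50, seed = 1)
  expect_true(all(bs$boot > 3 & bs$boot < 10))
  expect_true(bs$threshold > 3 && bs$threshold < 10)
  one <- bootstrap_cutoff(v, y, "high", n_boot = 1, seed = 2)
  expect_length(one$boot, 1)
  expect_equal(one$threshold, one$boot)
  # bootstrap SD decreases with training-set size
  set.seed(9)
  mk <- function(n) list(v = c(rnorm(n, 0), rnorm(n, 2)),
                         y = rep(c(0, 1), each = n))
  d1 <- mk(100); d2 <- mk(1000)
  s1 <- bootstrap_cutoff(d1$v, d1$y, "high", n_boot = 200, seed = 3)$summary[["sd"]]
  s2 <- bootstrap_cutoff(d2$v, d2$y, "high", n_boot = 200, seed = 3)$summary[["sd"]]
  expect_lt(s2, s1)
})

test_that("validation reproduces a hand-computed 2x2 table", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  y <- c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1)
  # threshold 5.5, direction high: TP = {6,7,9,10} -> sens 4/5;
  # TN = {1,2,4,5} -> spec 4/5
  out <- validate_cutoff(v, y, 5.5, "high")
  expect_equal(out$sensitivity, 0.8)
  expect_equal(out$specificity, 0.8)
  expect_equal(out$J, 0.6)
  perf <- validate_cutoff(c(1, 2, 10, 11), c(0, 0, 1, 1), 5, "high")
  expect_equal(unlist(perf), c(sensitivity = 1, specificity = 1, J = 1))
  all_pos <- validate_cutoff(v, y, 0, "high")
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
})

test_that("derived thresholds agree with dichotomize on group membership", {
  set.seed(5)
  nfl <- rlnorm(200, log(18), 0.5)
  y <- rbinom(200, 1, plogis(-2 + 1.5 * (log(nfl) - log(18))))
  if (sum(y) < 2) y[1:2] <- 1
  th <- youden_optimal_cutoff(nfl, y, "high")$threshold
  flags <- dichotomize(data.frame(nfl = nfl),
                       cutoff_set("nfl", th, "high"))
  expect_identical(flags$nfl, nfl > th)
})

test_that("the ten-year outcome window handles deaths and short follow-up", {
  out <- dementia_within_window(
    event = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    time = c(4, 12, 6, 6, 12),
    died = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out, c(TRUE, FALSE, FALSE, NA, FALSE))
})

test_that("the end-to-end derivation recovers a good threshold out of sample", {
  set.seed(61)
  v <- c(rnorm(600, 0), rnorm(600, 2))
  y <- rep(c(0, 1), each = 600)
  out <- derive_cutoff(v, y, "high", n_boot = 100, seed = 8)
  expect_equal(out$n_train, 960)
  expect_equal(out$n_test, 240)
  expect_lt(abs(out$threshold - 1), 0.25)
  expect_gt(out$validation$J, 0.5)
})
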