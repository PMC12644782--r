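#' Train/test split for cut-off derivation
#'
#' Random, disjoint, exhaustive split with `round(fraction * n)` training
#' subjects; reproducible under `seed`.
#'
#' @param subjects vector of subject identifiers (n >= 2).
#' @param fraction training fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return List with `train` and `test` identifier vectors.
#' @export
split_train_test <- function(subjects, fraction = 0.8, seed = 1) {
  n <- length(subjects)
  if (n < 2) stop("need at least two subjects to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_train <- round(fraction * n)
  if (n_train < 1) stop("training set would be empty")
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = subjects[idx], test = subjects[-idx])
}

#' Optimal cut-off by Youden's index
#'
#' Sweeps candidate thresholds at the midpoints between consecutive sorted
#' unique values and returns the threshold maximising
#' J = sensitivity + specificity - 1, with positivity defined by
#' `direction` (`"high"`: value > threshold is test-positive; `"low"`:
#' value < threshold). Ties are broken toward higher sensitivity, then the
#' smaller threshold.
#'
#' @param values numeric biomarker values.
#' @param outcomes logical or 0/1 outcome (both classes must be present).
#' @param direction `"high"` or `"low"`.
#' @return List `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_optimal_cutoff <- function(values, outcomes, direction = c("high", "low")) {
  direction <- match.arg(direction)
  outcomes <- as.logical(outcomes)
  keep <- !is.na(values) & !is.na(outcomes)
  values <- values[keep]; outcomes <- outcomes[keep]
  if (!any(outcomes) || all(outcomes)) stop("both outcome classes required")
  u <- sort(unique(values))
  if (length(u) < 2) {
    # no discriminating threshold exists
    return(list(threshold = u, J = 0, sensitivity = 1, specificity = 0))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(outcomes); n0 <- sum(!outcomes)
  # cumulative class counts at each unique value (vectorised sweep)
  f <- factor(values, levels = u)
  c1 <- cumsum(tabulate(f[outcomes], nbins = length(u)))[-length(u)]
  c0 <- cumsum(tabulate(f[!outcomes], nbins = length(u)))[-length(u)]
  if (direction == "high") {
    sens <- (n1 - c1) / n1   # cases strictly above the midpoint
    spec <- c0 / n0
  } else {
    sens <- c1 / n1          # cases strictly below the midpoint
    spec <- (n0 - c0) / n0
  }
  J <- sens + spec - 1
  best <- which(J > max(J) - 1e-12)
  best <- best[order(-sens[best], cand[best])][1]
  list(threshold = cand[best], J = J[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Bootstrap derivation of a biomarker positivity cut-off
#'
#' Nonparametric bootstrap over the training set: each of `n_boot`
#' resamples (with replacement, full training size) yields a Youden-optimal
#' threshold; the final cut-off aggregates them (median by default, mean by
#' option). Resamples containing a single outcome class are redrawn and
#' counted.
#'
#' @param values,outcomes,direction as in [youden_optimal_cutoff]
#'   (training data).
#' @param n_boot number of bootstrap iterations (the reference analysis
#'   used 5000).
#' @param seed integer seed.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return List `threshold`, `boot` (all bootstrap thresholds), `summary`
#'   (mean, sd, 2.5/97.5 percentiles), `n_redrawn`.
#' @export
bootstrap_cutoff <- function(values, outcomes, direction = c("high", "low"),
                             n_boot = 5000, seed = 1,
                             aggregate = c("median", "mean")) {
  direction <- match.arg(direction)
  aggregate <- match.arg(aggregate)
  if (n_boot < 1) stop("n_boot must be at least 1")
  outcomes <- as.logical(outcomes)
  n <- length(values)
  withr::with_seed(seed, {
    th <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        if (any(outcomes[i]) && !all(outcomes[i])) break
        n_redrawn <- n_redrawn + 1L
      }
      th[b] <- youden_optimal_cutoff(values[i], outcomes[i], direction)$threshold
    }
    list(threshold = if (aggregate == "median") stats::median(th) else mean(th),
         boot = th,
         summary = c(mean = mean(th), sd = stats::sd(th),
                     stats::quantile(th, c(.025, .975))),
         n_redrawn = n_redrawn)
  })
}

#' Validate a cut-off on held-out data
#'
#' @param values,outcomes held-out test data.
#' @param threshold finite threshold.
#' @param direction positivity direction as in [youden_optimal_cutoff].
#' @return List `sensitivity`, `specificity`, `J`.
#' @export
validate_cutoff <- function(values, outcomes, threshold,
                            direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  outcomes <- as.logical(outcomes)
  pos <- if (direction == "high") values > threshold else values < threshold
  sens <- sum(pos & outcomes) / sum(outcomes)
  spec <- sum(!pos & !outcomes) / sum(!outcomes)
  list(sensitivity = sens, specificity = spec, J = sens + spec - 1)
}

#' Derive and validate a biomarker cut-off end to end
#'
#' The full published procedure: random 80/20 train/test split, bootstrap
#' Youden-index maximisation on the training set, validation of the final
#' threshold on the held-out set.
#'
#' @inheritParams youden_optimal_cutoff
#' @inheritParams bootstrap_cutoff
#' @param fraction training fraction.
#' @return List `threshold`, `boot_summary`, `validation`
#'   (sensitivity/specificity/J on the test set), `n_train`, `n_test`.
#' @export
derive_cutoff <- function(values, outcomes, direction = c("high", "low"),
                          fraction = 0.8, n_boot = 5000, seed = 1) {
  direction <- match.arg(direction)
  sp <- split_train_test(seq_along(values), fraction, seed = seed)
  bs <- bootstrap_cutoff(values[sp$train], outcomes[sp$train], direction,
                         n_boot = n_boot, seed = seed + 1)
  val <- validate_cutoff(values[sp$test], outcomes[sp$test], bs$threshold,
                         direction)
  list(threshold = bs$threshold, boot_summary = bs$summary,
       validation = val, n_train = length(sp$train),
       n_test = length(sp$test))
}

#' Ten-year all-cause dementia outcome for cut-off derivation
#'
#' Builds the binary outcome used to derive cut-offs: dementia within 10
#' years of baseline. Subjects dying dementia-free before 10 years are
#' non-cases; subjects with less than 10 years of dementia-free follow-up
#' and no death are excluded (`NA`).
#'
#' @param event logical: dementia observed.
#' @param time years from baseline to dementia onset, death, or censoring.
#' @param died logical: subject died (dementia-free) at `time`.
#' @param window outcome window in years (default 10).
#' @return Logical vector (`NA` = excluded from the task).
#' @export
dementia_within_window <- function(event, time, died, window = 10) {
  out <- rep(NA, length(event))
  out[event & time <= window] <- TRUE
  out[!event & (time >= window | died)] <- FALSE
  out[event & time > window] <- FALSE
  out
}
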