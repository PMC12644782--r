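#' Synthetic cohort configuration
#'
#' Defines every knob of the synthetic-cohort generator: sample size, seed,
#' age-at-entry mixture (a young stratum entering below 78 and an old
#' stratum at 78+, emulating a population-based 60+ cohort with overall
#' median entry age near 72), covariate prevalences, log-normal biomarker
#' distributions with age slopes and inter-analyte correlation (targeting
#' the reference cohort's medians and IQRs), the true transition
#' intensities, the 6-year (<78) / 3-year (78+) visit schedule with a
#' 16-year administrative horizon, the censored-visit fraction, the dropout
#' mechanism and the cognitive-test emission parameters.
#'
#' @param n number of subjects (>= 1).
#' @param seed integer seed; every downstream random step derives from it.
#' @param p_young probability of entering below age 78.
#' @param entry_scale_young,entry_scale_old exponential scales (years) of
#'   age past 60 resp. 78 within each stratum.
#' @param max_entry_age truncation for entry ages.
#' @param p_female,p_university baseline prevalences.
#' @param disease_base,disease_age_slope Poisson mean of the chronic
#'   disease count: `disease_base + disease_age_slope * (age - 60)`.
#' @param comorbidity_prev named prevalences for ckd, heart, anemia, cvd,
#'   obesity.
#' @param biomarkers data frame of log-normal parameters per analyte (see
#'   [default_biomarker_params]).
#' @param biomarker_corr 6 x 6 positive semi-definite correlation matrix of
#'   the log-scale residuals.
#' @param true_params an [intensity_params] holding the true intensities;
#'   beta colnames must name covariate columns built by [generate_cohort]
#'   (z-scored biomarkers `<analyte>_z`, `sex`, `education`, comorbidity
#'   indicators, `n_diseases`).
#' @param p_mci_baseline probability of starting in MCI.
#' @param schedule list `young`, `old`, `switch` (visit spacings and age
#'   threshold).
#' @param max_followup administrative follow-up horizon in years.
#' @param censor_frac fraction of follow-up NC/MCI visits recorded only as
#'   the censored set \{NC, MCI\}.
#' @param dropout `"none"`, `"random"` (independent per-visit dropout
#'   hazard) or `"mar_age"` (all follow-up lost with probability logistic
#'   in baseline age). Dropped follow-up contributes no panel data.
#' @param dropout_args list: `p` (per-visit, random), `intercept`, `slope`,
#'   `ref_age` (mar_age).
#' @param emission list of cognitive-test emission parameters: `mci_shift`,
#'   `dem_shift`, `noise_sd`, `p_iadl1_nc`, `p_iadl1_mci`, `fn_error`.
#' @param visit_jitter half-width (years) of optional uniform jitter on
#'   follow-up visit ages (0 = exact schedule).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 2000, seed = 1, p_young = 0.6,
                          entry_scale_young = 8, entry_scale_old = 6,
                          max_entry_age = 95,
                          p_female = 0.615, p_university = 0.354,
                          disease_base = 1.6, disease_age_slope = 0.11,
                          comorbidity_prev = c(ckd = 0.334, heart = 0.225,
                                               anemia = 0.110, cvd = 0.060,
                                               obesity = 0.128),
                          biomarkers = default_biomarker_params(),
                          biomarker_corr = default_biomarker_corr(),
                          true_params = default_true_params(),
                          p_mci_baseline = 0.177,
                          schedule = list(young = 6, old = 3, switch = 78),
                          max_followup = 16, censor_frac = 0.05,
                          dropout = c("none", "random", "mar_age"),
                          dropout_args = list(p = 0.1, intercept = -2,
                                              slope = 0.25, ref_age = 75),
                          emission = list(mci_shift = -2, dem_shift = -3,
                                          noise_sd = 0.5, p_iadl1_nc = 0.1,
                                          p_iadl1_mci = 0.4, fn_error = 0.05),
                          visit_jitter = 0) {
  if (n < 1) stop("n must be at least 1")
  stopifnot(p_young >= 0, p_young <= 1, p_mci_baseline >= 0,
            p_mci_baseline <= 1, censor_frac >= 0, censor_frac <= 1)
  ev <- eigen(biomarker_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("biomarker_corr is not positive semi-definite")
  structure(as.list(environment()), class = "cohort_config")
}

#' Log-normal biomarker generator parameters
#'
#' `med72` is the median at age 72 (the reference cohort's overall median),
#' `slope` the log-scale change per year of age (calibrated to the young
#' vs old stratum medians) and `sdlog` the residual log-scale SD.
#' @return Data frame with rownames `ab42_40`, `ptau181`, `ptau217`,
#'   `ttau`, `nfl`, `gfap`.
#' @export
default_biomarker_params <- function() {
  data.frame(
    row.names = BIOMARKERS,
    med72 = c(0.06, 1.2, 0.10, 0.8, 18.3, 124.4),
    slope = c(-0.0114, 0.0397, 0.0554, 0.0139, 0.0485, 0.0424),
    sdlog = c(0.23, 0.55, 0.70, 0.64, 0.45, 0.52))
}

#' @rdname default_biomarker_params
#' @export
default_biomarker_corr <- function() {
  R <- matrix(0.3, 6, 6, dimnames = list(BIOMARKERS, BIOMARKERS))
  diag(R) <- 1
  R["ab42_40", -1] <- -0.2
  R[-1, "ab42_40"] <- -0.2
  R
}

#' Default true transition intensities
#'
#' Gompertz baselines (reference age 60) chosen to yield event flows of the
#' order seen in population-based 60+ cohorts over ~10 years of follow-up:
#' substantial MCI incidence and reversion, dementia arising from MCI, and
#' strongly age-graded mortality highest from dementia.
#'
#' @param beta optional covariate log-HR matrix (transitions x covariates).
#' @param ... passed to [intensity_params] (e.g. `age_break`, `beta_old`).
#' @return An [intensity_params].
#' @export
default_true_params <- function(beta = NULL, ...) {
  intensity_params(
    log_rate = log(c("NC->MCI" = 0.02, "MCI->NC" = 0.12, "MCI->DEM" = 0.03,
                     "NC->DEATH" = 0.005, "MCI->DEATH" = 0.01,
                     "DEM->DEATH" = 0.08)),
    shape = c("NC->MCI" = 0.07, "MCI->NC" = 0, "MCI->DEM" = 0.09,
              "NC->DEATH" = 0.095, "MCI->DEATH" = 0.09, "DEM->DEATH" = 0.05),
    beta = beta, ref_age = 60, ...)
}

#' Generate the baseline table
#'
#' Reproducible under `config$seed`. Biomarkers are positive log-normal
#' draws with age slopes and correlated residuals; covariates are drawn at
#' the configured prevalences (comorbidity odds are tilted with age).
#'
#' @param config a [cohort_config].
#' @return Data frame with `subject_id`, `age`, `sex` (1 = female),
#'   `education` (1 = university), `n_diseases`, comorbidity indicators and
#'   the six raw biomarker columns.
#' @export
generate_baseline <- function(config) {
  withr::with_seed(config$seed, generate_baseline_impl(config))
}

generate_baseline_impl <- function(config) {
  n <- config$n
  young <- stats::runif(n) < config$p_young
  age <- ifelse(young,
                60 + stats::rexp(n, 1 / config$entry_scale_young),
                78 + stats::rexp(n, 1 / config$entry_scale_old))
  age <- pmin(age, config$max_entry_age)
  age[young] <- pmin(age[young], 78 - 1e-3)
  sex <- as.integer(stats::runif(n) < config$p_female)
  education <- as.integer(stats::runif(n) < config$p_university)
  n_diseases <- stats::rpois(n, config$disease_base +
                               config$disease_age_slope * (age - 60))
  com <- sapply(names(config$comorbidity_prev), function(nm) {
    p0 <- config$comorbidity_prev[[nm]]
    # tilt prevalence with age, keeping the overall level near the target
    eta <- stats::qlogis(p0) + 0.08 * (age - 72)
    as.integer(stats::runif(n) < stats::plogis(eta))
  })
  bp <- config$biomarkers
  L <- t(chol(config$biomarker_corr + diag(1e-10, 6)))
  eps <- matrix(stats::rnorm(n * 6), n, 6) %*% t(L)
  bio <- sapply(seq_len(6), function(k)
    exp(log(bp$med72[k]) + bp$slope[k] * (age - 72) + bp$sdlog[k] * eps[, k]))
  colnames(bio) <- rownames(bp)
  data.frame(subject_id = seq_len(n), age = age, sex = sex,
             education = education, n_diseases = n_diseases, com, bio)
}

# Intensities out of `state` at ages `a` (vectorised over transitions).
intensities_from <- function(params, state, a, x) {
  s <- params$structure
  idx <- which(s$allowed[, 1] == state)
  if (!length(idx)) return(numeric(0))
  young <- !is.finite(params$age_break) || a <= params$age_break
  active <- params$cov_side == 0L | (params$cov_side == 1L & young) |
    (params$cov_side == 2L & !young)
  lp <- params$log_rate[idx] + params$shape[idx] * (a - params$ref_age)
  if (any(active))
    lp <- lp + as.vector(params$beta[idx, active, drop = FALSE] %*%
                           x[params$cov_idx[active]])
  stats::setNames(exp(lp), s$states[s$allowed[idx, 2]])
}

#' Simulate one continuous-time trajectory
#'
#' Exact event times are drawn from the time-inhomogeneous intensities by
#' thinning within unit age slices; each transition intensity is convex in
#' age (exponential in a linear function), so the slice maximum of the
#' total exit intensity is attained at a slice endpoint, which gives a
#' valid dominating rate for any sign of the Gompertz slopes.
#'
#' @param entry_age age at entry (years).
#' @param x covariate vector matching the params' covariates.
#' @param params an [intensity_params] (the truth).
#' @param start_state `"NC"` or `"MCI"`.
#' @param horizon latest age simulated.
#' @return Data frame `age`, `state` (labels); first row is the entry.
#' @export
simulate_trajectory <- function(entry_age, x = NULL, params,
                                start_state = "NC", horizon) {
  s <- params$structure
  x <- check_covariate_vector(params, x)
  state <- match(start_state, s$states)
  if (is.na(state)) stop("unknown start state: ", start_state)
  ages <- entry_age; states <- state
  age <- entry_age
  repeat {
    if (state == s$death || age >= horizon) break
    ev <- next_transition(params, state, age, horizon, x)
    if (is.null(ev)) break
    age <- ev$age; state <- ev$state
    ages <- c(ages, age); states <- c(states, state)
  }
  data.frame(age = ages, state = s$states[states])
}

next_transition <- function(params, state, age, horizon, x) {
  lam <- function(a) sum(intensities_from(params, state, a, x))
  # constant intensities: draw the exponential waiting time directly
  if (all(params$shape == 0) && !is.finite(params$age_break)) {
    tot <- lam(age)
    if (tot <= 0) return(NULL)
    t <- age + stats::rexp(1, tot)
    if (t >= horizon) return(NULL)
    q <- intensities_from(params, state, t, x)
    s <- params$structure
    dest <- sample(length(q), 1, prob = q / sum(q))
    return(list(age = t,
                state = s$allowed[which(s$allowed[, 1] == state)[dest], 2]))
  }
  lo <- age
  while (lo < horizon) {
    hi <- min(lo + 1, horizon)
    if (is.finite(params$age_break) && params$age_break > lo &&
        params$age_break < hi) hi <- params$age_break
    bound <- max(lam(lo), lam(hi))
    if (!is.finite(bound)) stop("non-finite intensity in simulation")
    t <- lo
    if (bound > 0) {
      repeat {
        t <- t + stats::rexp(1, bound)
        if (t > hi) break
        q <- intensities_from(params, state, t, x)
        tot <- sum(q)
        if (stats::runif(1) <= tot / bound) {
          dest <- sample(length(q), 1, prob = q / tot)
          s <- params$structure
          return(list(age = t,
                      state = s$allowed[which(s$allowed[, 1] == state)[dest], 2]))
        }
      }
    }
    lo <- hi
  }
  NULL
}

# Visit ages under the 6-year (<switch) / 3-year (>= switch) schedule.
schedule_visits <- function(entry_age, schedule, max_followup, jitter = 0) {
  visits <- entry_age
  t <- entry_age
  repeat {
    t <- t + if (t < schedule$switch) schedule$young else schedule$old
    if (t > entry_age + max_followup + 1e-9) break
    visits <- c(visits, t)
  }
  if (jitter > 0 && length(visits) > 1)
    visits[-1] <- visits[-1] + stats::runif(length(visits) - 1, -jitter, jitter)
  visits
}

#' Observe a trajectory through the visit schedule
#'
#' Visits occur at entry, then every 6 years while the current age is below
#' the switch age and every 3 years after; the state recorded is the path's
#' state at the visit age. Death is recorded at its exact age; if dementia
#' onset falls between the last visit and death without having been
#' observed, the final observation is coded death-with-dementia-interval.
#' A configurable fraction of follow-up NC/MCI visits is recorded only as
#' the censored set \{NC, MCI\}. Dropout truncates the record (dropped
#' follow-up, including death registration, contributes no panel data).
#'
#' @param path trajectory from [simulate_trajectory].
#' @param config a [cohort_config].
#' @param x named covariate vector stored on the record.
#' @param subject_id identifier.
#' @param seed optional seed (otherwise the caller's RNG stream is used).
#' @return A [panel_record].
#' @export
observe_panel <- function(path, config, x = numeric(0), subject_id = 1L,
                          seed = NULL) {
  if (!nrow(path)) stop("empty path")
  run <- function() observe_panel_impl(path, config, x, subject_id)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

observe_panel_impl <- function(path, config, x, subject_id) {
  entry <- path$age[1]
  death_age <- if (any(path$state == "DEATH"))
    path$age[match("DEATH", path$state)] else Inf
  dem_age <- if (any(path$state == "DEM"))
    path$age[match("DEM", path$state)] else Inf
  visits <- schedule_visits(entry, config$schedule, config$max_followup,
                            config$visit_jitter)
  visits <- visits[visits < death_age - 1e-9]
  vstate <- path$state[findInterval(visits, path$age)]
  codes <- c(NC = 0L, MCI = 1L, DEM = 2L)[vstate]

  # dropout truncates the follow-up sequence (baseline always kept)
  keep <- length(visits)
  if (config$dropout[1] == "random" && length(visits) > 1) {
    for (i in 2:length(visits))
      if (stats::runif(1) < config$dropout_args$p) { keep <- i - 1; break }
  } else if (config$dropout[1] == "mar_age") {
    p_drop <- stats::plogis(config$dropout_args$intercept +
                              config$dropout_args$slope *
                              (entry - config$dropout_args$ref_age))
    # optional cap keeps retention probabilities bounded away from zero
    # (positivity), as inverse-probability weighting presupposes
    p_drop <- min(p_drop, config$dropout_args$cap %||% 1)
    if (stats::runif(1) < p_drop) keep <- 1
  }
  dropped <- keep < length(visits)
  visits <- visits[seq_len(keep)]
  codes <- codes[seq_len(keep)]
  vstate <- vstate[seq_len(keep)]

  # censored {NC, MCI} visits (never the baseline, never dementia)
  if (config$censor_frac > 0 && length(visits) > 1) {
    cen <- which(codes[-1] %in% c(0L, 1L)) + 1L
    cen <- cen[stats::runif(length(cen)) < config$censor_frac]
    codes[cen] <- 9L
  }

  # exact death (registry), unless follow-up was dropped
  if (!dropped && is.finite(death_age) &&
      death_age <= entry + config$max_followup) {
    dcode <- if (dem_age < death_age) 4L else 3L
    dage <- death_age
    if (length(visits) && dage - visits[length(visits)] < 1e-6)
      dage <- visits[length(visits)] + 1e-6
    visits <- c(visits, dage)
    codes <- c(codes, dcode)
  }
  rec <- panel_record(subject_id, visits, codes, x = x)
  attr(rec, "dropped") <- dropped
  rec
}

#' Generate a full synthetic cohort
#'
#' Baseline table, true continuous-time trajectories, and the observed
#' interval-censored panel. Covariate columns available to the true
#' intensities (and to later fits) are the z-scored biomarkers
#' (`<analyte>_z`, standardised within the generated cohort), `sex`,
#' `education`, the comorbidity indicators and `n_diseases`.
#'
#' @param config a [cohort_config].
#' @return List `baseline` (with z columns), `panel` ([panel_data]),
#'   `paths`, `visit_states` (true state at each scheduled visit),
#'   `dropped` (logical), `config`.
#' @export
generate_cohort <- function(config) {
  baseline <- generate_baseline(config)
  for (a in BIOMARKERS)
    baseline[[paste0(a, "_z")]] <- as.numeric(zscore(baseline[[a]]))
  covs <- c("sex", "education", "n_diseases",
            names(config$comorbidity_prev), paste0(BIOMARKERS, "_z"))
  need <- config$true_params$cov_names
  if (!all(need %in% covs)) stop("true_params covariates not generated: ",
                                 setdiff(need, covs)[1])
  withr::with_seed(config$seed + 500000L, {
    start <- ifelse(stats::runif(config$n) < config$p_mci_baseline,
                    "MCI", "NC")
    horizon <- baseline$age + config$max_followup + config$schedule$young
    paths <- vector("list", config$n)
    recs <- vector("list", config$n)
    vs <- vector("list", config$n)
    for (i in seq_len(config$n)) {
      x <- unlist(baseline[i, need, drop = FALSE])
      paths[[i]] <- simulate_trajectory(baseline$age[i], x,
                                        config$true_params, start[i],
                                        horizon[i])
      xall <- unlist(baseline[i, covs, drop = FALSE])
      recs[[i]] <- observe_panel_impl(paths[[i]], config, xall, i)
      va <- recs[[i]]$ages[recs[[i]]$states %in% c(0L, 1L, 2L, 9L)]
      vs[[i]] <- data.frame(
        subject_id = i, visit_age = va,
        true_state = paths[[i]]$state[findInterval(va, paths[[i]]$age)],
        age_stratum = paste0(pmin(floor(baseline$age[i] / 10) * 10, 90), "s"))
    }
    list(baseline = baseline, panel = panel_data(recs), paths = paths,
         visit_states = do.call(rbind, vs),
         dropped = vapply(recs, function(r) isTRUE(attr(r, "dropped")),
                          logical(1)),
         config = config)
  })
}

#' Emit noisy cognitive test scores and functional indicators
#'
#' Turns true visit states into the raw inputs of the staging module: seven
#' tests over five domains (one affected domain per impaired subject is
#' shifted by `mci_shift`; dementia shifts all domains by `dem_shift`),
#' Gaussian test noise, IADL/ADL indicators consistent with the state up to
#' the configured error rate, and a pass-through dementia flag.
#'
#' @param visit_states data frame `subject_id`, `visit_age`, `true_state`,
#'   `age_stratum` (as produced by [generate_cohort]).
#' @param config a [cohort_config] (emission parameters).
#' @param seed integer seed.
#' @return Data frame in the layout required by [stage_cohort].
#' @export
emit_cognitive_tests <- function(visit_states, config, seed = config$seed + 1000000L) {
  battery <- data.frame(
    domain = c("executive", "memory", "visuospatial", "language", "language",
               "speed", "speed"),
    test = c("tmt_b", "free_recall", "mental_rotation", "category_fluency",
             "letter_fluency", "digit_cancellation", "pattern_comparison"))
  em <- config$emission
  withr::with_seed(seed, {
    ids <- unique(visit_states$subject_id)
    affected <- stats::setNames(sample(unique(battery$domain), length(ids),
                                       replace = TRUE), ids)
    out <- lapply(seq_len(nrow(visit_states)), function(i) {
      v <- visit_states[i, ]
      shift <- rep(0, nrow(battery))
      if (v$true_state == "MCI")
        shift[battery$domain == affected[[as.character(v$subject_id)]]] <-
          em$mci_shift
      if (v$true_state == "DEM") shift <- rep(em$dem_shift, nrow(battery))
      iadl <- if (v$true_state == "MCI") {
        if (stats::runif(1) < em$fn_error) 2L
        else as.integer(stats::runif(1) < em$p_iadl1_mci)
      } else as.integer(stats::runif(1) < em$p_iadl1_nc)
      data.frame(subject_id = v$subject_id, visit_age = v$visit_age,
                 age_stratum = v$age_stratum,
                 domain = battery$domain, test = battery$test,
                 value = shift + stats::rnorm(nrow(battery), 0, em$noise_sd),
                 iadl_impaired = iadl, adl_preserved = v$true_state != "DEM",
                 dementia_dx = v$true_state == "DEM")
    })
    do.call(rbind, out)
  })
}
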