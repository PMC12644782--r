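#' Fit the four-state model to panel data by maximum likelihood
#'
#' Maximises the interval-censored panel likelihood over the unconstrained
#' parameter vector (log baseline rates, Gompertz slopes, covariate log
#' hazard ratios) by quasi-Newton (BFGS) search with finite-difference
#' gradients computed in compiled code. The covariance matrix is the inverse
#' of the observed negative Hessian (finite differences) at the optimum.
#'
#' @param data a [panel_data] object.
#' @param covariates character vector of covariate names (columns of the
#'   records' `x`) entering the intensities; `NULL` for none.
#' @param structure a [transition_structure].
#' @param beta_transitions transitions receiving covariate effects; default
#'   the three cognitive transitions `NC->MCI`, `MCI->NC`, `MCI->DEM` (the
#'   transitions for which hazard ratios are reported). Use
#'   `structure$labels` for effects on every transition.
#' @param gompertz if `FALSE`, all Gompertz slopes are fixed at 0
#'   (constant baseline intensities).
#' @param ref_age reference age for the baseline log rates.
#' @param step piecewise-constant grid width (years).
#' @param age_break optional age threshold: covariate effects are estimated
#'   separately below (`:young`) and above (`:old`) the threshold, with
#'   straddling intervals split at it (see [age_dependent_fit]).
#' @param init optional [intensity_params] used as starting value; default
#'   is a crude occurrence/exposure estimate with zero slopes and betas.
#' @param control list: `maxit` (500), `reltol` (1e-10), `n_start` (1;
#'   additional starts jitter the initial value with fixed seeds and the
#'   best optimum is kept), `hessian` (TRUE).
#' @return An object of class `msm_fit` with elements `estimates` (named
#'   vector), `vcov`, `loglik`, `converged`, `params` (fitted
#'   [intensity_params]), `n_subjects`, `n_transitions` and bookkeeping.
#' @export
fit_msm <- function(data, covariates = NULL, structure = default_structure(),
                    beta_transitions = c("NC->MCI", "MCI->NC", "MCI->DEM"),
                    gompertz = TRUE, ref_age = 60, step = 1,
                    age_break = NULL, init = NULL, control = list()) {
  if (length(data) == 0) stop("data is empty")
  ctl <- utils::modifyList(
    list(maxit = 500, reltol = 1e-10, n_start = 1, hessian = TRUE), control)
  covariates <- covariates %||% character(0)
  beta_transitions <- intersect(structure$labels, beta_transitions)

  counts <- count_transitions(data, structure)
  if (is.null(init))
    init <- crude_init(counts, structure, covariates, ref_age, age_break)
  if (!identical(init$cov_names, covariates))
    stop("init covariates do not match `covariates`")

  flat <- flatten_panel(data, covariates)
  ml <- model_list(init)
  theta0 <- params_to_vector(init)
  free <- free_mask(init, beta_transitions, gompertz)
  free_idx <- which(free)

  neg_fn <- function(th_free) {
    th <- theta0; th[free_idx] <- th_free
    ll <- cpp_loglik(th, ml, flat, step)
    if (!is.finite(ll)) 1e10 else -ll
  }
  neg_gr <- function(th_free) {
    th <- theta0; th[free_idx] <- th_free
    g <- cpp_loglik_grad(th, ml, flat, step, free_idx, FALSE)
    if (anyNA(g)) rep(0, length(g)) else -g
  }

  starts <- list(theta0[free_idx])
  if (ctl$n_start > 1) {
    for (k in seq_len(ctl$n_start - 1))
      starts[[k + 1]] <- theta0[free_idx] +
        withr::with_seed(1000 + k, stats::rnorm(length(free_idx), 0, 0.3))
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, neg_fn, neg_gr, method = "BFGS",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  theta <- theta0; theta[free_idx] <- best$par
  grad <- cpp_loglik_grad(theta, ml, flat, step, free_idx, TRUE)
  gnorm <- if (anyNA(grad)) Inf else max(abs(grad))
  converged <- best$convergence == 0 && gnorm < 1e-2 * (1 + abs(best$value))

  vcov_free <- NULL
  if (isTRUE(ctl$hessian)) {
    H <- tryCatch(
      stats::optimHess(best$par, neg_fn, neg_gr,
                       control = list(ndeps = rep(1e-5, length(free_idx)))),
      error = function(e) NULL)
    if (!is.null(H)) {
      H <- (H + t(H)) / 2
      vcov_free <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov_free) && any(diag(vcov_free) < 0)) vcov_free <- NULL
    }
  }
  p <- length(theta)
  V <- matrix(NA_real_, p, p, dimnames = list(names(theta), names(theta)))
  if (!is.null(vcov_free)) {
    V[free_idx, free_idx] <- (vcov_free + t(vcov_free)) / 2
    V[!free, ] <- 0; V[, !free] <- 0
    V[free_idx, free_idx] <- (vcov_free + t(vcov_free)) / 2
  }

  fitted <- vector_to_params(theta, init)
  structure(
    list(estimates = theta, vcov = V, loglik = -best$value,
         converged = converged, grad_norm = gnorm,
         vcov_available = !is.null(vcov_free),
         params = fitted, free = free, covariates = covariates,
         n_subjects = length(data), n_transitions = counts$transitions,
         step = step, gompertz = gompertz,
         beta_transitions = beta_transitions,
         optim = best[c("convergence", "counts")]),
    class = "msm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

free_mask <- function(params, beta_transitions, gompertz) {
  s <- params$structure
  nt <- n_trans(s)
  nf <- ncol(params$beta)
  free <- c(rep(TRUE, nt), rep(isTRUE(gompertz), nt),
            rep(s$labels %in% beta_transitions, nf))
  free
}

# Crude occurrence/exposure starting values: observed direct transitions over
# approximate person-years at risk, zero slopes and betas.
crude_init <- function(counts, structure, covariates, ref_age, age_break) {
  rate <- (counts$transitions + 0.5) / (counts$person_years[
    structure$states[structure$allowed[, 1]]] + 2)
  beta <- if (length(covariates))
    matrix(0, n_trans(structure), length(covariates),
           dimnames = list(structure$labels, covariates)) else NULL
  intensity_params(structure, log_rate = log(pmin(pmax(rate, 1e-4), 2)),
                   shape = 0, beta = beta, ref_age = ref_age,
                   age_break = age_break)
}

#' Count observed transitions and participants at risk
#'
#' Counts consecutive-visit pairs exhibiting each observed state change
#' (known -> known states; exact deaths are attributed from the last known
#' living state when unambiguous, and death-with-dementia observations count
#' one entry into dementia and one DEM -> DEATH transition). Censored-set
#' observations are excluded from numerators but their subjects remain in the
#' denominators. Also reports the number of distinct participants observed in
#' each source state and approximate person-years per state.
#'
#' @param data a [panel_data] object.
#' @param structure a [transition_structure].
#' @return List with `transitions` (named count vector over allowed
#'   transitions), `pairs` (K x K matrix of observed known-state pairs),
#'   `participants` (named by state) and `person_years`.
#' @export
count_transitions <- function(data, structure = default_structure()) {
  K <- length(structure$states)
  pairs <- matrix(0L, K, K, dimnames = list(structure$states, structure$states))
  py <- stats::setNames(rep(0, K), structure$states)
  seen <- lapply(seq_len(K), function(i) character(0))
  for (r in data) {
    obs <- code_to_obs(r$states)
    last_known <- NA_integer_; last_age <- NA_real_
    for (i in seq_along(r$ages)) {
      ot <- obs$otype[i]
      if (ot == OBS_KNOWN) {
        st <- obs$ostate[i]
        if (!is.na(last_known)) {
          pairs[last_known, st] <- pairs[last_known, st] + 1L
          py[last_known] <- py[last_known] + (r$ages[i] - last_age)
        }
        seen[[st]] <- union(seen[[st]], as.character(r$subject_id))
        last_known <- st; last_age <- r$ages[i]
      } else if (ot == OBS_DEATH && !is.na(last_known)) {
        pairs[last_known, structure$death] <-
          pairs[last_known, structure$death] + 1L
        py[last_known] <- py[last_known] + (r$ages[i] - last_age)
      } else if (ot == OBS_DEATH_DEM && !is.na(last_known)) {
        dem <- match("DEM", structure$states)
        if (last_known != dem) pairs[last_known, dem] <- pairs[last_known, dem] + 1L
        pairs[dem, structure$death] <- pairs[dem, structure$death] + 1L
        py[last_known] <- py[last_known] + (r$ages[i] - last_age) / 2
        py[dem] <- py[dem] + (r$ages[i] - last_age) / 2
      }
    }
  }
  tr <- stats::setNames(integer(n_trans(structure)), structure$labels)
  for (t in seq_len(n_trans(structure)))
    tr[t] <- pairs[structure$allowed[t, 1], structure$allowed[t, 2]]
  list(transitions = tr, pairs = pairs,
       participants = vapply(seen, length, integer(1)) |>
         stats::setNames(structure$states),
       person_years = py)
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Four-state panel Markov model fit\n")
  cat("  subjects:", x$n_subjects, " log-likelihood:",
      format(x$loglik, digits = 8), "\n")
  cat("  converged:", x$converged, " (max |score| =",
      format(x$grad_norm, digits = 3), ")\n")
  if (length(x$covariates)) {
    cat("Hazard ratios:\n")
    print(hazard_ratio_table(x), digits = 3)
  }
  invisible(x)
}

#' Hazard ratio and Wald 95% confidence interval for one covariate effect
#'
#' @param fit an `msm_fit`.
#' @param transition transition label, e.g. `"MCI->DEM"`.
#' @param covariate covariate (effective column) name; with an age break use
#'   e.g. `"nfl_z:young"`.
#' @return Named vector `hr`, `lo95`, `hi95` (CI is `NA` when the covariance
#'   is unavailable), plus `beta` and `se` as attributes-free extra entries.
#' @export
hazard_ratio <- function(fit, transition, covariate) {
  nm <- paste0("beta:", transition, ":", covariate)
  if (!nm %in% names(fit$estimates))
    stop("no such effect in the fit: ", nm)
  b <- fit$estimates[[nm]]
  se <- sqrt(fit$vcov[nm, nm])
  c(hr = exp(b),
    lo95 = if (is.na(se)) NA_real_ else exp(b - 1.96 * se),
    hi95 = if (is.na(se)) NA_real_ else exp(b + 1.96 * se),
    beta = b, se = se)
}

# All covariate effects of a fit as a data frame (Table-2-like shape).
hazard_ratio_table <- function(fit) {
  out <- NULL
  for (tr in fit$beta_transitions)
    for (cv in colnames(fit$params$beta)) {
      h <- hazard_ratio(fit, tr, cv)
      out <- rbind(out, data.frame(transition = tr, covariate = cv,
                                   estimate = h[["beta"]], se = h[["se"]],
                                   hr = h[["hr"]], lo95 = h[["lo95"]],
                                   hi95 = h[["hi95"]]))
    }
  out
}

#' Fit with age-dependent covariate effects
#'
#' Covariate effects enter as separate log hazard ratios on age segments at
#' or below `threshold_age` (`:young`) and above it (`:old`); intervals
#' straddling the threshold are split there inside the piecewise-constant
#' probability computation. A side with no exposure is flagged
#' non-identifiable (its CI is unavailable / huge).
#'
#' @inheritParams fit_msm
#' @param threshold_age age threshold in years (default 78).
#' @return An `msm_fit`; effective covariate columns are named
#'   `<cov>:young` and `<cov>:old`.
#' @export
age_dependent_fit <- function(data, covariates, threshold_age = 78,
                              structure = default_structure(), ...) {
  rng <- range(unlist(lapply(data, `[[`, "ages")))
  if (threshold_age < rng[1])
    message("threshold below all observed ages: reduces to a single ",
            "old-age effect")
  if (threshold_age > rng[2])
    message("threshold above all observed ages: reduces to a single ",
            "young-age effect")
  fit_msm(data, covariates = covariates, structure = structure,
          age_break = threshold_age, ...)
}
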