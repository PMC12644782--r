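#' Gompertz intensity parameters with proportional covariate effects
#'
#' Each allowed transition r -> s has intensity
#' \deqn{q_{rs}(a, x) = \exp(\lambda^*_{rs} + \gamma_{rs}(a - a_{ref}) +
#'   \beta_{rs}^T x)}
#' where \eqn{a} is age (the model time scale), \eqn{\lambda^*} is the log
#' hazard at the reference age, \eqn{\gamma} the Gompertz slope (1/year) and
#' \eqn{\beta} transition-specific log hazard ratios. Covariate effects may
#' optionally differ below and above an age threshold (`age_break`), in which
#' case `beta` applies at ages `<= age_break` and `beta_old` above it for the
#' covariates named in `age_dependent`.
#'
#' @param structure a [transition_structure].
#' @param log_rate numeric, per transition (named by transition label or in
#'   structure order): log hazard at `ref_age`.
#' @param shape numeric, per transition (recycled): Gompertz slope, 1/year.
#' @param beta numeric matrix, transitions x covariates, with covariate
#'   colnames; `NULL` for no covariates.
#' @param ref_age reference age in years (default 60, a typical youngest
#'   entry age; centring stabilises the optimisation).
#' @param age_break optional age threshold (years) at which covariate effects
#'   switch.
#' @param age_dependent character vector of covariate names whose effects
#'   switch at `age_break` (default: all columns of `beta`).
#' @param beta_old matrix like `beta` holding the effects above `age_break`
#'   for the age-dependent covariates (default: equal to `beta`).
#' @return An object of class `intensity_params`.
#' @examples
#' p <- intensity_params(log_rate = log(c(.10, .05, .08, .02, .03, .15)))
#' build_intensity_matrix(p, age = 70)
#' @export
intensity_params <- function(structure = default_structure(), log_rate,
                             shape = 0, beta = NULL, ref_age = 60,
                             age_break = NULL, age_dependent = NULL,
                             beta_old = NULL) {
  nt <- n_trans(structure)
  log_rate <- resolve_per_transition(log_rate, structure, "log_rate")
  shape <- resolve_per_transition(shape, structure, "shape")
  if (is.null(beta)) {
    beta <- matrix(0, nt, 0)
  } else {
    beta <- as.matrix(beta)
    if (nrow(beta) != nt) stop("beta must have one row per allowed transition")
    if (is.null(colnames(beta))) stop("beta columns must be named after covariates")
  }
  cov_names <- colnames(beta) %||% character(0)
  if (!is.null(age_break)) {
    if (is.null(age_dependent)) age_dependent <- cov_names
    bad <- setdiff(age_dependent, cov_names)
    if (length(bad)) stop("age_dependent names not in beta: ", bad[1])
    if (is.null(beta_old)) beta_old <- beta
    beta_old <- as.matrix(beta_old)
  } else {
    age_dependent <- character(0)
  }
  # Expand to effective columns: always-on columns plus young/old pairs.
  eff_beta <- NULL; cov_idx <- integer(0); cov_side <- integer(0)
  eff_names <- character(0)
  for (j in seq_along(cov_names)) {
    nm <- cov_names[j]
    if (nm %in% age_dependent) {
      eff_beta <- cbind(eff_beta, beta[, j], beta_old[, j])
      cov_idx <- c(cov_idx, j, j)
      cov_side <- c(cov_side, 1L, 2L)
      eff_names <- c(eff_names, paste0(nm, ":young"), paste0(nm, ":old"))
    } else {
      eff_beta <- cbind(eff_beta, beta[, j])
      cov_idx <- c(cov_idx, j)
      cov_side <- c(cov_side, 0L)
      eff_names <- c(eff_names, nm)
    }
  }
  if (is.null(eff_beta)) eff_beta <- matrix(0, nt, 0)
  colnames(eff_beta) <- eff_names
  rownames(eff_beta) <- structure$labels
  structure(
    list(structure = structure, log_rate = log_rate, shape = shape,
         beta = eff_beta, cov_names = cov_names, cov_idx = cov_idx,
         cov_side = cov_side, ref_age = ref_age,
         age_break = if (is.null(age_break)) NA_real_ else age_break),
    class = "intensity_params")
}

resolve_per_transition <- function(x, structure, what) {
  nt <- n_trans(structure)
  if (!is.null(names(x))) {
    out <- rep(0, nt)
    i <- trans_index(structure, names(x))
    out[i] <- unname(x)
  } else if (length(x) == 1L) {
    out <- rep(x, nt)
  } else if (length(x) == nt) {
    out <- unname(x)
  } else {
    stop(what, " must have length 1 or ", nt, " (or be named by transition)")
  }
  names(out) <- structure$labels
  out
}

#' @export
print.intensity_params <- function(x, ...) {
  cat("Gompertz intensity parameters (ref age ", x$ref_age, ")\n", sep = "")
  tab <- data.frame(rate = exp(x$log_rate), shape = x$shape)
  if (ncol(x$beta)) tab <- cbind(tab, x$beta)
  print(round(tab, 4))
  if (is.finite(x$age_break))
    cat("Covariate effects switch at age", x$age_break, "\n")
  invisible(x)
}

# List handed to the C++ routines.
model_list <- function(params, n_x = length(params$cov_names)) {
  s <- params$structure
  list(K = length(s$states), death = s$death,
       from = as.integer(s$allowed[, 1]), to = as.integer(s$allowed[, 2]),
       log_rate = unname(params$log_rate), shape = unname(params$shape),
       beta = unname(params$beta),
       cov_idx = as.integer(params$cov_idx),
       cov_side = as.integer(params$cov_side),
       ref_age = params$ref_age, age_break = params$age_break,
       n_x = n_x)
}

# Flat parameter vector layout: [log_rate (nt), shape (nt), vec(beta)].
params_to_vector <- function(params) {
  nt <- n_trans(params$structure)
  v <- c(params$log_rate, params$shape, as.vector(params$beta))
  names(v) <- c(paste0("lograte:", params$structure$labels),
                paste0("shape:", params$structure$labels),
                if (ncol(params$beta))
                  paste0("beta:", rep(params$structure$labels, ncol(params$beta)),
                         ":", rep(colnames(params$beta), each = nt)))
  v
}

vector_to_params <- function(theta, template) {
  nt <- n_trans(template$structure)
  nf <- ncol(template$beta)
  out <- template
  out$log_rate[] <- theta[seq_len(nt)]
  out$shape[] <- theta[nt + seq_len(nt)]
  if (nf > 0) out$beta[] <- theta[2 * nt + seq_len(nt * nf)]
  out
}
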