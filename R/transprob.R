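#' Transition probability matrix over an age interval
#'
#' Solves the Kolmogorov forward equations for the age-dependent intensity
#' matrix. The default method is a piecewise-constant approximation: the
#' interval is divided into sub-intervals of width at most `step` (split
#' additionally at the covariate age break, if any), and Q is evaluated at
#' each sub-interval midpoint; P is the ordered product of the matrix
#' exponentials. `method = "ode"` integrates the forward equations with an
#' adaptive solver (deSolve) and serves as an internal oracle for the
#' piecewise approximation.
#'
#' Disallowed one-step transitions (NC -> DEM) can still have positive
#' probability through intermediate states; that is the intended semantics of
#' the interval-censored model.
#'
#' @param params an [intensity_params].
#' @param age0,age1 interval endpoints in years, `age1 >= age0`.
#' @param x covariate vector (see [build_intensity_matrix]).
#' @param step grid width in years for the piecewise-constant method.
#' @param method `"piecewise"` (default) or `"ode"`.
#' @return A row-stochastic K x K matrix P(age0, age1).
#' @export
transition_probability <- function(params, age0, age1, x = NULL, step = 1,
                                   method = c("piecewise", "ode")) {
  method <- match.arg(method)
  if (age1 < age0) stop("invalid interval: age1 < age0")
  if (step <= 0) stop("step must be positive")
  x <- check_covariate_vector(params, x)
  s <- params$structure
  if (method == "piecewise") {
    P <- cpp_interval_p(model_list(params), age0, age1, rbind(x), step)
  } else {
    P <- ode_interval_p(params, age0, age1, x)
  }
  dimnames(P) <- list(s$states, s$states)
  P
}

ode_interval_p <- function(params, age0, age1, x) {
  K <- length(params$structure$states)
  if (age1 - age0 < 1e-12) return(diag(K))
  deriv <- function(a, p, parms) {
    P <- matrix(p, K, K)
    Q <- build_intensity_matrix(params, a,
                                if (length(x)) stats::setNames(x, params$cov_names))
    list(as.vector(P %*% Q))
  }
  # Integrate through the age break without stepping over the discontinuity.
  times <- c(age0, age1)
  if (is.finite(params$age_break) && params$age_break > age0 &&
      params$age_break < age1)
    times <- c(age0, params$age_break, age1)
  out <- deSolve::ode(y = as.vector(diag(K)), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  matrix(out[nrow(out), -1], K, K)
}
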