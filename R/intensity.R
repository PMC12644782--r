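#' Build the transition intensity matrix at a given age
#'
#' Returns the generator matrix Q of the continuous-time Markov model at age
#' `age` for covariate vector `x`: off-diagonal entries are the transition
#' intensities of the allowed transitions, disallowed entries are 0, each row
#' sums to zero and the death row is identically zero.
#'
#' @param params an [intensity_params] object.
#' @param age age in years.
#' @param x named numeric covariate vector matching `params$cov_names`
#'   (omit or `NULL` when the model has no covariates).
#' @return A K x K matrix with state dimnames.
#' @export
build_intensity_matrix <- function(params, age, x = NULL) {
  if (!is.finite(age)) stop("age must be finite")
  s <- params$structure
  x <- check_covariate_vector(params, x)
  K <- length(s$states)
  Q <- matrix(0, K, K, dimnames = list(s$states, s$states))
  young <- !is.finite(params$age_break) || age <= params$age_break
  active <- params$cov_side == 0L | (params$cov_side == 1L & young) |
    (params$cov_side == 2L & !young)
  for (t in seq_len(n_trans(s))) {
    lp <- params$log_rate[t] + params$shape[t] * (age - params$ref_age)
    if (any(active))
      lp <- lp + sum(params$beta[t, active] * x[params$cov_idx[active]])
    Q[s$allowed[t, 1], s$allowed[t, 2]] <-
      Q[s$allowed[t, 1], s$allowed[t, 2]] + exp(lp)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

check_covariate_vector <- function(params, x) {
  p <- length(params$cov_names)
  if (p == 0L) return(numeric(0))
  if (is.null(x) || length(x) != p)
    stop("covariate vector must have length ", p, " (",
         paste(params$cov_names, collapse = ", "), ")")
  if (!is.null(names(x))) {
    if (!setequal(names(x), params$cov_names))
      stop("covariate names do not match params$cov_names")
    x <- x[params$cov_names]
  }
  unname(as.numeric(x))
}
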