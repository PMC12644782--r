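#' Hazard-ratio curve for a spline-coded covariate
#'
#' For a fit whose covariates include the two restricted-cubic-spline
#' columns of `basis` (named `<prefix>rcs1`, `<prefix>rcs2`), computes
#' \eqn{HR(z) = \exp(c(z)^T \hat\beta)} with \eqn{c(z) = B(z) - B(z_{ref})}
#' and the median (middle knot) as reference, so `HR(ref) = 1` with a
#' degenerate confidence interval. Pointwise 95% CIs use the delta method on
#' the log scale with the covariance of the spline coefficients.
#'
#' @param fit an `msm_fit` produced with the spline-coded covariate.
#' @param transition transition label.
#' @param basis the [spline_basis] used to code the covariate.
#' @param z grid of covariate values.
#' @param prefix covariate column prefix used in the fit (default `""`,
#'   i.e. columns `rcs1`, `rcs2`).
#' @return Data frame `z`, `hr`, `lo95`, `hi95`, `extrapolated` (flagging
#'   grid points outside the data range of the basis).
#' @export
spline_hr_curve <- function(fit, transition, basis, z, prefix = "") {
  cols <- paste0(prefix, c("rcs1", "rcs2"))
  nms <- paste0("beta:", transition, ":", cols)
  if (!all(nms %in% names(fit$estimates)))
    stop("fit does not contain spline coefficients ", paste(cols, collapse = ", "),
         " for ", transition)
  beta <- fit$estimates[nms]
  V <- fit$vcov[nms, nms]
  Cz <- eval_basis(basis, z) - matrix(eval_basis(basis, basis$ref),
                                      length(z), 2, byrow = TRUE)
  eta <- as.vector(Cz %*% beta)
  se <- sqrt(pmax(rowSums((Cz %*% V) * Cz), 0))
  data.frame(z = z, hr = exp(eta),
             lo95 = exp(eta - 1.96 * se), hi95 = exp(eta + 1.96 * se),
             extrapolated = z < basis$range[1] | z > basis$range[2])
}
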