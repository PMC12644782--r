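#' Inverse-probability-of-attrition weights
#'
#' Attrition after the baseline assessment is modelled by logistic
#' regression of retention (has follow-up data) on baseline age, sex,
#' education, number of chronic diseases and the six z-scored biomarker
#' levels; retained subjects are reweighted by the inverse of their fitted
#' retention probability (optionally stabilised by the marginal retention
#' rate and truncated at symmetric percentiles) and the model is refitted
#' with the weights multiplying the log-likelihood contributions.
#'
#' @name ipw
NULL

#' Fit the dropout (retention) model
#'
#' @param baseline data frame of baseline variables.
#' @param retained logical: subject has follow-up data.
#' @param predictors character vector of predictor column names.
#' @return List `coef`, `p_retain` (fitted retention probabilities),
#'   `separation` flag, `model` (the glm fit).
#' @export
fit_dropout_model <- function(baseline, retained,
                              predictors = setdiff(names(baseline), "subject_id")) {
  retained <- as.logical(retained)
  if (!any(retained) || all(retained)) stop("both outcome classes required")
  const <- vapply(baseline[predictors],
                  function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) stop("constant predictor: ", predictors[const][1])
  df <- baseline[predictors]
  df$.retained <- retained
  fit <- suppressWarnings(
    stats::glm(.retained ~ ., family = stats::binomial(), data = df))
  co <- stats::coef(fit)
  separation <- !fit$converged || any(abs(co[-1]) > 10, na.rm = TRUE)
  if (separation) {
    warning("possible separation in the dropout model; coefficients capped")
    co[-1] <- pmin(pmax(co[-1], -10), 10)
    eta <- as.vector(cbind(1, as.matrix(df[predictors])) %*% co)
    p <- stats::plogis(eta)
  } else {
    p <- stats::fitted(fit)
  }
  list(coef = co, p_retain = pmin(pmax(p, 1e-8), 1), separation = separation,
       model = fit)
}

#' Compute inverse-probability-of-attrition weights
#'
#' @param p_retain fitted retention probabilities in (0, 1].
#' @param retained logical retention indicator (dropped-out subjects get
#'   weight 0; they contribute no panel data).
#' @param stabilize multiply by the marginal retention rate (default TRUE).
#' @param truncate_pct symmetric percentile truncation of the retained
#'   subjects' weights (default `c(0.01, 0.99)`; `NULL` to disable).
#' @return Numeric weight per subject.
#' @export
compute_ipw <- function(p_retain, retained, stabilize = TRUE,
                        truncate_pct = c(0.01, 0.99)) {
  retained <- as.logical(retained)
  if (any(p_retain <= 0 & retained)) stop("retained subject with p_retain = 0")
  w <- ifelse(retained, 1 / p_retain, 0)
  if (stabilize) w <- w * mean(retained)
  if (!is.null(truncate_pct)) {
    q <- stats::quantile(w[retained], truncate_pct)
    w[retained] <- pmin(pmax(w[retained], q[1]), q[2])
  }
  w
}

#' Refit the multistate model with attrition weights
#'
#' @param data a [panel_data] object.
#' @param weights numeric vector, one weight per record (in data order);
#'   each record's log-likelihood contribution is multiplied by its weight.
#' @param ... passed to [fit_msm].
#' @return An `msm_fit`.
#' @export
weighted_refit <- function(data, weights, ...) {
  if (length(weights) != length(data)) stop("one weight per record required")
  reweighted <- lapply(seq_along(data), function(i) {
    r <- data[[i]]; r$weight <- weights[i]; r
  })
  fit_msm(panel_data(reweighted), ...)
}
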