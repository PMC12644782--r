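#' Panel log-likelihood
#'
#' `loglik_subject` returns one subject's weighted log-likelihood
#' contribution under the interval-censored Markov model; `loglik_total`
#' sums contributions over a panel data set.
#'
#' The contribution is a forward pass over state distributions: known states
#' condition the distribution, censored \{NC, MCI\} observations restrict it
#' (joint treatment across intervals, not independent marginal sums), and an
#' exact death at age t contributes the density
#' \eqn{\sum_s P(t_0, t)[\cdot, s]\, q_{s,DEATH}(t)}. Dementia status at
#' death is always ascertained (registry and chart review), so the death
#' codes partition the deaths and the sum runs over s in \{NC, MCI\} for a
#' dementia-free death and is restricted to s = DEM for a death with
#' dementia (encoding onset in the preceding interval when dementia was not
#' already observed). A subject with a single observation contributes 0. A
#' zero-probability sequence returns `-Inf`.
#'
#' @param record a [panel_record].
#' @param data a [panel_data] object.
#' @param params an [intensity_params].
#' @param step piecewise-constant grid width in years.
#' @return Scalar log-likelihood (weighted by the record weights).
#' @export
loglik_subject <- function(record, params, step = 1) {
  loglik_total(panel_data(list(record)), params, step)
}

#' @rdname loglik_subject
#' @export
loglik_total <- function(data, params, step = 1) {
  if (length(data) == 0) return(0)
  flat <- flatten_panel(data, params$cov_names)
  cpp_loglik(params_to_vector(params), model_list(params), flat, step)
}
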