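#' Run a full analysis over a cohort
#'
#' Orchestrates biomarker preparation and model fitting for one analysis
#' mode, producing Table-2-shaped hazard-ratio tables (per transition of
#' interest: NC->MCI, MCI->NC, MCI->DEM) with transition/participant
#' counts, fit diagnostics and a machine-readable settings log. All
#' artifacts are reproducible under the seed recorded in the config.
#'
#' Modes: `"continuous-spline"` (z-scored biomarker through a 3-knot
#' restricted cubic spline, median reference), `"dichotomized"` (high/low
#' at the predefined cut-offs), `"combinations"` (0-3 elevated among
#' p-tau217, NfL, GFAP, none as reference), `"age-dependent"` (separate
#' effects at or below / above 78), `"sex-stratified"` (separate fits per
#' stratum), `"exclude-baseline-mci"`, `"ipw"` (attrition-weighted refit).
#' The adjustment set is `"basic"` (sex, education) or `"full"` (plus
#' chronic kidney disease, heart disease, cerebrovascular disease, anemia,
#' obesity).
#'
#' @param cohort a list as returned by [generate_cohort] (elements
#'   `baseline`, `panel`; `dropped` is required for mode `"ipw"`), or a
#'   [panel_data] plus `baseline` given separately.
#' @param biomarker analyte name, e.g. `"nfl"` (ignored for
#'   `"combinations"`).
#' @param mode analysis mode, see above.
#' @param adjustment `"basic"` or `"full"`.
#' @param cutoffs a `cutoff_set` for the dichotomised modes.
#' @param gompertz,step,control passed to [fit_msm].
#' @param outdir optional directory: writes `hr_table.csv`,
#'   `transition_counts.csv` and `run_log.json`.
#' @return List with `hr_table` (data frame: transition, covariate,
#'   estimate, se, hr, lo95, hi95), `counts`, `fit` (or named list of fits
#'   when stratified), `settings`.
#' @export
run_analysis <- function(cohort, biomarker = "nfl",
                         mode = c("continuous-spline", "dichotomized",
                                  "combinations", "age-dependent",
                                  "sex-stratified", "exclude-baseline-mci",
                                  "ipw"),
                         adjustment = c("basic", "full"),
                         cutoffs = predefined_cutoffs(), gompertz = TRUE,
                         step = 1, control = list(), outdir = NULL) {
  mode <- match.arg(mode)
  adjustment <- match.arg(adjustment)
  baseline <- cohort$baseline
  panel <- cohort$panel
  adj <- c("sex", "education")
  if (adjustment == "full")
    adj <- c(adj, "ckd", "heart", "cvd", "anemia", "obesity")
  bad <- setdiff(adj, names(baseline))
  if (length(bad)) stop("unknown covariate in adjustment set: ", bad[1])

  # analysis covariates per mode, appended to each record's x
  extra <- switch(mode,
    "continuous-spline" = {
      z <- zscore(impute_below_lod(baseline[[biomarker]], 0))
      basis <- rcs_basis(as.numeric(z))
      stats::setNames(as.data.frame(basis$basis),
                      paste0(biomarker, "_", colnames(basis$basis)))
    },
    "combinations" = {
      cnt <- count_elevated(dichotomize(baseline, cutoffs))
      data.frame(elev1 = as.integer(cnt == 1), elev2 = as.integer(cnt == 2),
                 elev3 = as.integer(cnt == 3))
    },
    {
      flags <- dichotomize(baseline[biomarker], cutoffs)
      stats::setNames(data.frame(as.integer(flags[[biomarker]])),
                      paste0(biomarker, "_high"))
    })
  panel <- add_covariates(panel, cbind(baseline[adj], extra))
  covs <- c(names(extra), adj)

  fit1 <- function(pd, ...) fit_msm(pd, covariates = covs, gompertz = gompertz,
                                    step = step, control = control, ...)
  fits <- switch(mode,
    "sex-stratified" = {
      covs <- setdiff(covs, "sex")
      list(female = fit1(panel[baseline$sex == 1]),
           male = fit1(panel[baseline$sex == 0]))
    },
    "exclude-baseline-mci" = {
      first_mci <- vapply(panel, function(r) r$states[1] == 1L, logical(1))
      list(all = fit1(panel[!first_mci]))
    },
    "age-dependent" = list(all = fit1(panel, age_break = 78)),
    "ipw" = {
      if (is.null(cohort$dropped)) stop("mode 'ipw' needs cohort$dropped")
      dm <- fit_dropout_model(
        baseline, retained = !cohort$dropped,
        predictors = c("age", "sex", "education", "n_diseases",
                       paste0(BIOMARKERS, "_z")))
      w <- compute_ipw(dm$p_retain, !cohort$dropped)
      keep <- !cohort$dropped
      list(all = weighted_refit(panel[keep], w[keep], covariates = covs,
                                gompertz = gompertz, step = step,
                                control = control))
    },
    list(all = fit1(panel)))

  hr <- do.call(rbind, lapply(names(fits), function(nm) {
    tb <- hazard_ratio_table(fits[[nm]])
    tb <- tb[tb$covariate %in% c(names(extra),
                                 paste0(names(extra), ":young"),
                                 paste0(names(extra), ":old")), ]
    if (length(fits) > 1) tb <- cbind(stratum = nm, tb)
    tb
  }))
  counts <- count_transitions(panel)
  settings <- list(mode = mode, biomarker = biomarker,
                   adjustment = adjustment, gompertz = gompertz, step = step,
                   n_subjects = length(panel),
                   seed = cohort$config$seed %||% NA,
                   package_version = as.character(utils::packageVersion("cogmsm")))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(hr, file.path(outdir, "hr_table.csv"), row.names = FALSE)
    utils::write.csv(data.frame(transition = names(counts$transitions),
                                n = as.integer(counts$transitions)),
                     file.path(outdir, "transition_counts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(settings, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(hr_table = hr, counts = counts, fit = fits, settings = settings)
}

# Attach extra covariate columns (data frame, one row per record) to records.
add_covariates <- function(panel, df) {
  panel_data(lapply(seq_along(panel), function(i) {
    r <- panel[[i]]
    new <- unlist(df[i, , drop = FALSE])
    r$x <- c(r$x[setdiff(names(r$x), names(new))], new)
    r
  }))
}
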