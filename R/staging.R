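#' Cognitive staging from neuropsychological test scores
#'
#' The battery covers five domains (executive function, episodic memory,
#' visuospatial abilities, language, perceptual speed). Raw test scores are
#' standardised against age-stratum-specific baseline norms; when a domain
#' has several tests the test z-scores are averaged. MCI requires a domain
#' z-score at or below -1.5, largely preserved functional independence (at
#' most one impaired IADL and preserved basic ADLs) and no dementia
#' diagnosis. CIND applies the same cognitive rule without the functional
#' criteria. Norms are frozen at baseline: follow-up visits are scored
#' against the baseline means and SDs.
#'
#' @name staging
NULL

#' Baseline norms for z-scoring test scores
#'
#' @param df data frame with columns `age_stratum`, `domain`, `test`,
#'   `mean`, `sd` (all SDs positive).
#' @return A `staging_norms` object.
#' @export
staging_norms <- function(df) {
  stopifnot(all(c("age_stratum", "domain", "test", "mean", "sd") %in% names(df)))
  if (any(df$sd <= 0)) stop("all norm SDs must be positive")
  structure(df, class = c("staging_norms", "data.frame"))
}

# Norms computed from a baseline score table (one row per subject/test).
norms_from_baseline <- function(scores) {
  agg <- stats::aggregate(value ~ age_stratum + domain + test, scores,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  staging_norms(data.frame(agg[1:3], mean = agg$value[, "mean"],
                           sd = agg$value[, "sd"]))
}

#' Per-domain z-scores for one visit
#'
#' @param scores data frame with columns `domain`, `test`, `value` (raw
#'   scores for one subject-visit).
#' @param norms a [staging_norms] object covering every (stratum, domain,
#'   test) present.
#' @param age_stratum the subject's age stratum key.
#' @return Named numeric vector of domain z-scores (domains with no
#'   available test are absent).
#' @export
compute_domain_zscores <- function(scores, norms, age_stratum) {
  scores <- scores[!is.na(scores$value), , drop = FALSE]
  if (!nrow(scores)) return(stats::setNames(numeric(0), character(0)))
  key <- paste(age_stratum, scores$domain, scores$test)
  nkey <- paste(norms$age_stratum, norms$domain, norms$test)
  i <- match(key, nkey)
  if (anyNA(i)) stop("norms missing for: ", key[is.na(i)][1])
  z <- (scores$value - norms$mean[i]) / norms$sd[i]
  out <- tapply(z, scores$domain, mean)[unique(scores$domain)]
  stats::setNames(as.numeric(out), names(out))
}

#' Classify a visit as NC / MCI / DEM
#'
#' `classify_mci` applies the full MCI rule (cognitive + functional);
#' `classify_cind` ignores the functional criteria. Subjects failing only
#' the functional criterion are classified NC (the states partition into
#' exactly NC/MCI/DEM) and flagged via the `functional_fail` attribute.
#'
#' @param domain_z named numeric vector of domain z-scores (at least one).
#' @param iadl_impaired number of impaired instrumental ADLs.
#' @param adl_preserved logical: basic ADLs preserved.
#' @param dementia_dx logical: clinical dementia diagnosis.
#' @return `"NC"`, `"MCI"` or `"DEM"`; attribute `functional_fail` is TRUE
#'   when the cognitive criterion is met but the functional one is not.
#' @export
classify_mci <- function(domain_z, iadl_impaired, adl_preserved, dementia_dx) {
  if (dementia_dx) return("DEM")
  if (!length(domain_z) || all(is.na(domain_z)))
    stop("no domain z-scores available: visit state is censored {NC, MCI}")
  impaired <- min(domain_z, na.rm = TRUE) <= -1.5
  functional_ok <- iadl_impaired <= 1 && adl_preserved
  out <- if (impaired && functional_ok) "MCI" else "NC"
  attr(out, "functional_fail") <- impaired && !functional_ok
  out
}

#' @rdname classify_mci
#' @export
classify_cind <- function(domain_z, dementia_dx) {
  if (dementia_dx) return("DEM")
  if (!length(domain_z) || all(is.na(domain_z)))
    stop("no domain z-scores available: visit state is censored {NC, MCI}")
  if (min(domain_z, na.rm = TRUE) <= -1.5) "MCI" else "NC"
}

#' Stage a cohort's visits
#'
#' @param visits data frame with one row per subject-visit-test: columns
#'   `subject_id`, `visit_age`, `age_stratum`, `domain`, `test`, `value`,
#'   `iadl_impaired`, `adl_preserved`, `dementia_dx`.
#' @param norms a [staging_norms]; default computed from the baseline
#'   (first) visit of each subject.
#' @param rule `"mci"` (default) or `"cind"`.
#' @return Data frame `subject_id`, `visit_age`, `state` (`NA` when no
#'   domain is scoreable: censored \{NC, MCI\}), `min_domain_z`,
#'   `functional_fail`.
#' @export
stage_cohort <- function(visits, norms = NULL, rule = c("mci", "cind")) {
  rule <- match.arg(rule)
  if (is.null(norms)) {
    first_age <- stats::ave(visits$visit_age, visits$subject_id, FUN = min)
    norms <- norms_from_baseline(visits[visits$visit_age == first_age, ])
  }
  keys <- unique(visits[c("subject_id", "visit_age")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    v <- visits[visits$subject_id == keys$subject_id[i] &
                  visits$visit_age == keys$visit_age[i], ]
    z <- tryCatch(compute_domain_zscores(v, norms, v$age_stratum[1]),
                  error = function(e) numeric(0))
    usable <- length(z) > 0 && !all(is.na(z))
    st <- if (v$dementia_dx[1]) "DEM"
      else if (!usable) NA_character_
      else if (rule == "mci")
        classify_mci(z, v$iadl_impaired[1], v$adl_preserved[1], FALSE)
      else classify_cind(z, FALSE)
    data.frame(subject_id = keys$subject_id[i], visit_age = keys$visit_age[i],
               state = as.character(st),
               min_domain_z = if (usable) min(z, na.rm = TRUE) else NA_real_,
               functional_fail = isTRUE(attr(st, "functional_fail")))
  })
  do.call(rbind, out)
}
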