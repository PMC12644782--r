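#' Blood biomarker panel utilities
#'
#' The six serum biomarkers are the amyloid-beta 42/40 ratio (unitless) and
#' p-tau181, p-tau217, total tau, NfL and GFAP (pg/mL). A low ratio is the
#' at-risk direction for Abeta42/40; high values are at risk for the others.
#'
#' @name biomarkers
NULL

BIOMARKERS <- c("ab42_40", "ptau181", "ptau217", "ttau", "nfl", "gfap")

#' Predefined dichotomisation cut-offs
#'
#' Cut-offs derived in the source cohort by bootstrap Youden-index
#' maximisation for 10-year all-cause dementia prediction: 0.057 for the
#' Abeta42/40 ratio (low at risk), 1.512 pg/mL p-tau181, 0.134 pg/mL
#' p-tau217, 0.832 pg/mL t-tau, 20.171 pg/mL NfL and 142.515 pg/mL GFAP
#' (high at risk).
#'
#' @return A `cutoff_set`: data frame with `analyte`, `threshold`,
#'   `direction` (`"low"`/`"high"` = at-risk side).
#' @export
predefined_cutoffs <- function() {
  cutoff_set(
    analyte = BIOMARKERS,
    threshold = c(0.057, 1.512, 0.134, 0.832, 20.171, 142.515),
    direction = c("low", "high", "high", "high", "high", "high"))
}

#' @rdname predefined_cutoffs
#' @param analyte,threshold,direction vectors defining the set.
#' @export
cutoff_set <- function(analyte, threshold, direction) {
  stopifnot(all(threshold > 0), all(direction %in% c("low", "high")))
  structure(data.frame(analyte = analyte, threshold = threshold,
                       direction = direction),
            class = c("cutoff_set", "data.frame"))
}

#' Replace values below the limit of detection by zero
#'
#' Single-value imputation under a not-missing-at-random assumption: values
#' strictly below the LOD are set to 0. Idempotent.
#'
#' @param values nonnegative concentrations (NA allowed, passed through).
#' @param lod nonnegative limit of detection.
#' @return The imputed vector, with attribute `n_imputed`.
#' @export
impute_below_lod <- function(values, lod) {
  if (lod < 0) stop("lod must be nonnegative")
  if (any(values < 0, na.rm = TRUE)) stop("negative concentration")
  low <- !is.na(values) & values < lod
  values[low] <- 0
  attr(values, "n_imputed") <- sum(low)
  values
}

#' Standardise to z-scores
#'
#' @param values numeric with at least two distinct non-missing values.
#' @return Z-scored vector with attributes `mean` and `sd` (denominator
#'   n - 1) allowing the inverse transform.
#' @export
zscore <- function(values) {
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  z <- (values - m) / s
  attr(z, "mean") <- m
  attr(z, "sd") <- s
  z
}

#' Restricted cubic spline basis with three knots
#'
#' Harrell's restricted truncated-power construction: column 1 is the
#' identity; column 2 is the single restricted cubic term
#' \deqn{\frac{(z-t_1)_+^3 - (z-t_2)_+^3 (t_3-t_1)/(t_3-t_2) +
#'   (z-t_3)_+^3 (t_2-t_1)/(t_3-t_2)}{(t_3-t_1)^2}}
#' normalised by the squared boundary-knot span so both columns are on
#' comparable scale. The basis is linear beyond the boundary knots. Default
#' knots are the empirical 25th/50th/75th percentiles; the median (middle
#' knot) is the reference value used by [spline_hr_curve].
#'
#' @param z numeric values (typically z-scored biomarker).
#' @param knots three strictly increasing knots.
#' @return List of class `spline_basis`: `basis` (n x 2 matrix), `knots`,
#'   `ref` (middle knot) and `range` (data range, for extrapolation flags).
#' @export
rcs_basis <- function(z, knots = NULL) {
  if (is.null(knots))
    knots <- unname(stats::quantile(z, c(.25, .5, .75), na.rm = TRUE))
  if (length(knots) != 3 || any(diff(knots) <= 0))
    stop("knots must be three strictly increasing values")
  B <- cbind(z, rcs_term(z, knots))
  colnames(B) <- c("rcs1", "rcs2")
  structure(list(basis = B, knots = knots, ref = knots[2],
                 range = range(z, na.rm = TRUE)),
            class = "spline_basis")
}

rcs_term <- function(z, knots) {
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  pp3 <- function(u) pmax(u, 0)^3
  (pp3(z - t1) - pp3(z - t2) * (t3 - t1) / (t3 - t2) +
     pp3(z - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
}

# Evaluate the two basis columns at new values.
eval_basis <- function(basis, z) {
  cbind(rcs1 = z, rcs2 = rcs_term(z, basis$knots))
}

#' Dichotomise a biomarker panel at predefined cut-offs
#'
#' At-risk means strictly beyond the threshold in the risk direction
#' (strictly below for Abeta42/40, strictly above otherwise); values equal
#' to the threshold are not at risk. Missing analytes yield `NA` flags.
#'
#' @param panel data frame with analyte columns.
#' @param cutoffs a `cutoff_set` covering all analytes present.
#' @return Data frame of logical at-risk flags, one column per analyte.
#' @export
dichotomize <- function(panel, cutoffs = predefined_cutoffs()) {
  present <- intersect(names(panel), cutoffs$analyte)
  missing_cut <- setdiff(intersect(names(panel), BIOMARKERS), present)
  if (length(missing_cut)) stop("no cut-off for: ", missing_cut[1])
  out <- lapply(present, function(a) {
    row <- cutoffs[cutoffs$analyte == a, ]
    v <- panel[[a]]
    if (row$direction == "low") v < row$threshold else v > row$threshold
  })
  names(out) <- present
  as.data.frame(out)
}

#' Count elevated biomarkers among p-tau217, NfL and GFAP
#'
#' @param flags data frame (or list) of at-risk flags containing `ptau217`,
#'   `nfl` and `gfap`.
#' @return Integer 0-3 per subject; `NA` when any of the three is missing.
#' @export
count_elevated <- function(flags) {
  need <- c("ptau217", "nfl", "gfap")
  if (!all(need %in% names(flags))) stop("flags must include ", paste(need, collapse = ", "))
  flags$ptau217 + flags$nfl + flags$gfap
}
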