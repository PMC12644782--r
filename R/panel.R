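#' Panel records: one subject's observation sequence
#'
#' A panel record holds a subject's visit ages, the observation made at each
#' visit, baseline covariates and an attrition weight. Observations are coded
#' as in the panel CSV dialect: `0` NC, `1` MCI, `2` DEM, `3` exact death,
#' dementia-free (dementia status at death is always ascertained), `4` exact
#' death with dementia (onset in the preceding interval when not already
#' observed), `9` censored state set \{NC, MCI\} (alive and dementia-free,
#' stage unknown).
#'
#' @param subject_id scalar identifier.
#' @param ages strictly increasing visit ages in years.
#' @param states integer observation codes (same length as `ages`).
#' @param x named numeric vector of baseline covariates (may be empty).
#' @param weight nonnegative attrition weight (default 1).
#' @return An object of class `panel_record`.
#' @export
panel_record <- function(subject_id, ages, states, x = numeric(0), weight = 1) {
  if (length(ages) != length(states)) stop("ages and states lengths differ")
  if (length(ages) > 1 && any(diff(ages) <= 0))
    stop("visit ages must be strictly increasing (ties with death age included)")
  states <- as.integer(states)
  if (!all(states %in% c(0:4, 9L))) stop("unknown state code")
  death_pos <- which(states %in% c(3L, 4L))
  if (length(death_pos) > 1 || (length(death_pos) == 1 &&
                                death_pos != length(states)))
    stop("death may appear only as the final observation")
  if (weight < 0) stop("weight must be nonnegative")
  structure(list(subject_id = subject_id, ages = as.numeric(ages),
                 states = states, x = x, weight = as.numeric(weight)),
            class = "panel_record")
}

#' @export
print.panel_record <- function(x, ...) {
  lab <- c(`0` = "NC", `1` = "MCI", `2` = "DEM", `3` = "DEATH",
           `4` = "DEATH(dem)", `9` = "{NC,MCI}")
  cat("Subject ", x$subject_id, " (w = ", signif(x$weight, 3), "): ",
      paste(sprintf("%.1f:%s", x$ages, lab[as.character(x$states)]),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Assemble a list of panel records into a panel data set
#'
#' @param records list of [panel_record] objects.
#' @return An object of class `panel_data` (a validated list of records).
#' @export
panel_data <- function(records) {
  ok <- vapply(records, inherits, logical(1), "panel_record")
  if (!all(ok)) stop("all elements must be panel_record objects")
  structure(records, class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("Panel data:", length(x), "subjects,",
      sum(vapply(x, function(r) length(r$ages), integer(1))), "observations\n")
  invisible(x)
}

#' @export
`[.panel_data` <- function(x, i) panel_data(unclass(x)[i])

# Map CSV state codes to internal (otype, ostate) pairs; ostate is 1-based.
code_to_obs <- function(code) {
  otype <- integer(length(code)); ostate <- integer(length(code))
  known <- code %in% 0:2
  otype[known] <- OBS_KNOWN; ostate[known] <- code[known] + 1L
  otype[code == 9L] <- OBS_CENSORED
  otype[code == 3L] <- OBS_DEATH
  otype[code == 4L] <- OBS_DEATH_DEM
  list(otype = otype, ostate = ostate)
}

# Flatten panel data for the C++ likelihood. `covariates` fixes the column
# order; records must carry all of them.
flatten_panel <- function(data, covariates = character(0)) {
  n <- length(data)
  lens <- vapply(data, function(r) length(r$ages), integer(1))
  ptr <- c(0L, cumsum(lens))
  ages <- unlist(lapply(data, `[[`, "ages"), use.names = FALSE)
  codes <- unlist(lapply(data, `[[`, "states"), use.names = FALSE)
  obs <- code_to_obs(codes)
  X <- matrix(0, n, length(covariates),
              dimnames = list(NULL, covariates))
  for (i in seq_len(n)) {
    if (length(covariates)) {
      xi <- data[[i]]$x[covariates]
      if (anyNA(xi)) stop("subject ", data[[i]]$subject_id,
                          " is missing covariates")
      X[i, ] <- xi
    }
  }
  list(ptr = as.integer(ptr), ages = ages, otype = as.integer(obs$otype),
       ostate = as.integer(obs$ostate - 1L), X = X,
       w = vapply(data, `[[`, numeric(1), "weight"))
}

#' Read and write panel data as CSV
#'
#' One row per observation: `subject_id`, `age`, `state` (codes as in
#' [panel_record]), an optional `weight` column, and any further columns
#' treated as per-subject baseline covariates (values from the first row of
#' each subject are used).
#'
#' @param path file path.
#' @param df a data frame in the same layout (for `as_panel_data`).
#' @return A [panel_data] object; `write_panel_csv` returns `path` invisibly.
#' @export
read_panel_csv <- function(path) {
  as_panel_data(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_panel_csv
#' @export
as_panel_data <- function(df) {
  stopifnot(all(c("subject_id", "age", "state") %in% names(df)))
  covs <- setdiff(names(df), c("subject_id", "age", "state", "weight"))
  recs <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$age), ]
    panel_record(d$subject_id[1], d$age, d$state,
                 x = unlist(d[1, covs, drop = FALSE]),
                 weight = if ("weight" %in% names(d)) d$weight[1] else 1)
  })
  panel_data(unname(recs))
}

#' @rdname read_panel_csv
#' @param data a [panel_data] object.
#' @export
write_panel_csv <- function(data, path) {
  rows <- lapply(data, function(r) {
    d <- data.frame(subject_id = r$subject_id, age = r$ages, state = r$states,
                    weight = r$weight)
    for (nm in names(r$x)) d[[nm]] <- r$x[[nm]]
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
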