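#' State space and allowed transitions of the cognitive ageing model
#'
#' The model has four states: normal cognition (`NC`), mild cognitive
#' impairment (`MCI`), dementia (`DEM`) and death (`DEATH`). Death is
#' absorbing. By default the direct transition NC -> DEM is not allowed
#' (subjects observed to make it are assumed to have passed through an
#' unobserved MCI phase) and MCI <-> NC is the only reversible pair.
#'
#' @param states character vector of state labels; the last state is the
#'   absorbing death state.
#' @param allowed two-column character matrix of allowed (from, to) pairs.
#' @return An object of class `transition_structure` with elements `states`,
#'   `allowed` (integer matrix) and `labels` (e.g. `"NC->MCI"`).
#' @examples
#' default_structure()
#' @export
transition_structure <- function(states, allowed) {
  if (anyDuplicated(states)) stop("duplicate state labels")
  idx <- matrix(match(allowed, states), ncol = 2)
  if (anyNA(idx)) stop("allowed transitions refer to unknown states")
  death <- length(states)
  if (any(idx[, 1] == death)) stop("the death state must be absorbing")
  if (any(idx[, 1] == idx[, 2])) stop("self-transitions are not allowed")
  structure(
    list(states = states, allowed = idx,
         labels = paste0(states[idx[, 1]], "->", states[idx[, 2]]),
         death = death),
    class = "transition_structure")
}

#' @rdname transition_structure
#' @export
default_structure <- function() {
  transition_structure(
    states = c("NC", "MCI", "DEM", "DEATH"),
    allowed = rbind(c("NC", "MCI"), c("MCI", "NC"), c("MCI", "DEM"),
                    c("NC", "DEATH"), c("MCI", "DEATH"), c("DEM", "DEATH")))
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure:", paste(x$states, collapse = " "), "\n")
  cat("Allowed:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

n_trans <- function(structure) nrow(structure$allowed)

trans_index <- function(structure, transition) {
  i <- match(transition, structure$labels)
  if (anyNA(i)) stop("unknown transition: ", transition[is.na(i)][1])
  i
}

#' State codes used in the panel CSV dialect
#'
#' `0` NC, `1` MCI, `2` DEM, `3` exact death, `4` death with dementia onset in
#' the preceding interval, `9` censored state set \{NC, MCI\}.
#' @keywords internal
#' @name panel-codes
NULL

# Internal observation-type codes (match src/msm_core.cpp)
OBS_KNOWN <- 1L
OBS_CENSORED <- 2L
OBS_DEATH <- 3L
OBS_DEATH_DEM <- 4L
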