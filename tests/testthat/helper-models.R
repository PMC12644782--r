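# Shared fixtures: small models and panels built in code.

# Constant-intensity reference model: NC->MCI .10, MCI->NC .05, MCI->DEM .08,
# NC->DEATH .02, MCI->DEATH .03, DEM->DEATH .15.
constant_params <- function(beta = NULL, ...) {
  intensity_params(log_rate = log(c(.10, .05, .08, .02, .03, .15)),
                   shape = 0, beta = beta, ...)
}

# A K=4 structure in which only NC -> DEATH is possible (pure death).
pure_death_structure <- function() {
  transition_structure(states = c("NC", "MCI", "DEM", "DEATH"),
                       allowed = rbind(c("NC", "DEATH")))
}

pure_death_params <- function(rate = 0.1, shape = 0, ref_age = 60) {
  intensity_params(pure_death_structure(), log_rate = log(rate),
                   shape = shape, ref_age = ref_age)
}

# Fixture panels with at most three observations, exercising every
# observation kind (codes: 0 NC, 1 MCI, 2 DEM, 3 death, 4 death+dementia,
# 9 censored {NC,MCI}).
fixture_records <- function() {
  list(
    panel_record("kk", c(70, 76, 80), c(0, 1, 2)),
    panel_record("cens", c(70, 76, 80), c(0, 9, 1)),
    panel_record("cens2", c(70, 73, 79), c(1, 9, 9)),
    panel_record("cens_start", c(70, 76), c(9, 2)),
    panel_record("death", c(70, 76, 80), c(0, 1, 3)),
    panel_record("death_dem", c(70, 76, 80), c(0, 9, 4)),
    panel_record("dem_then_death", c(70, 76, 80), c(1, 2, 4)),
    panel_record("stay", c(70, 76), c(0, 0)))
}

# Small cohort for fit-based unit tests: constant intensities, one binary
# covariate acting on MCI->DEM.
small_cohort <- function(n = 400, seed = 7, beta_mci_dem = log(2),
                         covariate = "nfl_z") {
  beta <- matrix(0, 6, 1, dimnames = list(NULL, covariate))
  beta[3, 1] <- beta_mci_dem
  tp <- intensity_params(
    log_rate = log(c(.06, .10, .08, .015, .02, .15)), shape = 0,
    beta = beta)
  generate_cohort(cohort_config(n = n, seed = seed, true_params = tp,
                                censor_frac = 0.05))
}
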