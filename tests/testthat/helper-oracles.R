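# Independent oracles, deliberately implemented differently from the
# package's likelihood (grid path enumeration with first-order one-step
# probabilities, not matrix exponentials).

# Brute-force discretised path-sum log-likelihood for one record.
# Enumerating all state paths on a grid of width dt collapses to a forward
# dynamic program with one-step matrix I + Q(a) * dt.
oracle_loglik <- function(record, params, dt = 0.05) {
  s <- params$structure
  K <- length(s$states)
  xs <- if (length(params$cov_names))
    stats::setNames(record$x[params$cov_names], params$cov_names) else NULL
  ages <- record$ages
  codes <- record$states
  alpha <- numeric(K)
  if (codes[1] %in% 0:2) alpha[codes[1] + 1] <- 1 else alpha[1:2] <- 1
  ll <- 0
  for (i in seq_along(ages)[-1]) {
    nstep <- max(1L, round((ages[i] - ages[i - 1]) / dt))
    h <- (ages[i] - ages[i - 1]) / nstep
    for (k in seq_len(nstep)) {
      a <- ages[i - 1] + (k - 0.5) * h
      M <- diag(K) + build_intensity_matrix(params, a, xs) * h
      alpha <- alpha %*% M
    }
    alpha <- as.numeric(alpha)
    code <- codes[i]
    if (code %in% 0:2) {
      keep <- numeric(K); keep[code + 1] <- alpha[code + 1]
      alpha <- keep
    } else if (code == 9) {
      alpha[3:K] <- 0
    } else {
      Q <- build_intensity_matrix(params, ages[i], xs)
      dem <- match("DEM", s$states)
      sources <- if (code == 3) setdiff(seq_len(K), c(dem, s$death)) else dem
      return(ll + log(sum(alpha[sources] * Q[sources, s$death])))
    }
    tot <- sum(alpha)
    if (tot <= 0) return(-Inf)
    ll <- ll + log(tot)
    alpha <- alpha / tot
  }
  ll * record$weight
}

# Survival under a pure Gompertz death hazard by numerical quadrature.
gompertz_survival <- function(rate, shape, a0, a1, ref_age = 60) {
  exp(-stats::integrate(function(a) rate * exp(shape * (a - ref_age)),
                        a0, a1, rel.tol = 1e-12)$value)
}
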