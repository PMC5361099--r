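# Independent quadrature oracle for posterior checks: naive-summation
# Poisson tails (no ppois/pgamma) on a fine log grid, trapezoid moments.
# The grid support matches the model definition (flat prior on
# [C*_min/1e3, C*_max*1e3]) but is 10x finer than the package grid and is
# built through a separate code path.
oracle_posterior <- function(dv, signal, k = NULL, n = 20001) {
  if (is.null(k)) k <- rep(1, length(dv))
  cstar <- log(2) / dv
  cg <- exp(seq(log(min(cstar) / 1e3), log(max(cstar) * 1e3),
                length.out = n))
  logL <- rep(0, n)
  for (j in seq_along(dv)) {
    lam <- cg * dv[j]
    if (signal[j] == 0) {
      logL <- logL - lam
    } else {
      below <- rep(0, n)
      for (m in 0:(k[j] - 1))
        below <- below + exp(m * log(lam) - lam - lgamma(m + 1))
      logL <- logL + log(pmax(1 - below, 1e-300))
    }
  }
  L <- exp(logL - max(logL))
  w <- c(diff(cg) / 2, 0) + c(0, diff(cg) / 2)
  z <- sum(w * L)
  mu <- sum(w * L * cg) / z
  s2 <- sum(w * L * (cg - mu)^2) / z
  list(mean = mu, sd = sqrt(s2), grid = cg, density = L / z)
}

# memoized reduced-replicate calibration tables shared by the design and
# acceptance tests (one Monte-Carlo calibration per mode per test run)
calibration_cache <- new.env(parent = emptyenv())
get_calibration <- function(mode, replicates = 300, seed = 11) {
  key <- paste(mode, replicates, seed, sep = "_")
  if (is.null(calibration_cache[[key]]))
    calibration_cache[[key]] <- calibrate_design(mode, replicates = replicates,
                                                 seed = seed)
  calibration_cache[[key]]
}
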