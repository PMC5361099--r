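test_that("calibration tables behave physically", {
  ts <- get_calibration("synergistic")
  td <- get_calibration("digital")
  # attainable precision improves monotonically as x -> 1 (up to MC jitter,
  # which the monotone envelope used for inversion removes)
  mono_s <- synpcr:::monotone_sigma(ts)
  expect_true(all(diff(mono_s$sigma) <= 0))
  expect_lt(min(ts$sigma_inf), 0.15)
  expect_gt(max(ts$sigma_inf), 0.45)
  # the Ct information never hurts: synergistic beats digital at every x
  expect_true(all(ts$sigma_inf < td$sigma_inf))
  # margins grow as the ladder flattens
  expect_gte(ts$delta_n[nrow(ts)], ts$delta_n[1])
  # JSON round-trip
  path <- tempfile(fileext = ".json")
  write_calibration(ts, path)
  back <- read_calibration(path)
  expect_equal(as.data.frame(back), as.data.frame(ts), tolerance = 1e-12)
  expect_equal(attr(back, "mode"), "synergistic")
})

test_that("precision saturates as the active-stripe margin grows", {
  # sigma(deltaN) for a fixed ladder is nonincreasing up to MC noise
  lay_of <- function(dn) {
    dv <- log(2) * 0.6^seq(-dn, dn)
    assay_layout(dilution = rep(1, length(dv)), volume = dv)
  }
  sig <- sapply(c(2, 6, 12), function(dn) {
    p <- precision_profile(lay_of(dn), 1, replicates = 120,
                           mode = "synergistic", seed = 7)
    p$sigma
  })
  expect_gt(sig[1], sig[2])
  expect_lt(abs(sig[3] - sig[2]) / sig[2], 0.15)   # saturated regime
})

test_that("common-ratio inversion is the inverse of the calibrated relation", {
  ts <- get_calibration("synergistic")
  ms <- synpcr:::monotone_sigma(ts)
  for (s in c(0.45, 0.3, 0.2)) {
    d <- common_ratio_for_precision(s, ts)
    back <- approx(ms$x, ms$sigma, xout = d$x)$y
    expect_equal(back, s, tolerance = 0.02)
  }
  expect_error(common_ratio_for_precision(0.01, ts), "library_copies >= ")
})

test_that("designed assays follow the explicit recipe", {
  ts <- get_calibration("synergistic")
  lay <- design_assay(0.4, 1e2, ts, c_minus = 5)
  x <- lay$common_ratio
  n_core <- ceiling(log(1e2) / -log(x))
  expect_equal(n_partitions(lay),
               lay$library_copies * (n_core + 2 * lay$delta_n))
  # largest characteristic concentration sits deltaN steps above C+
  cstar <- log(2) / modulations(lay)
  expect_equal(max(cstar), 5 * 1e2 * x^(-lay$delta_n), tolerance = 1e-9)
  # modulations form the geometric ladder with each copy repeated k times
  dv <- unique(modulations(lay))
  expect_equal(dv[-1] / dv[-length(dv)], rep(x, length(dv) - 1),
               tolerance = 1e-9)
  # degenerate single-point range collapses to the margins
  lay1 <- design_assay(0.4, 1, ts)
  expect_equal(n_partitions(lay1),
               lay1$library_copies * (1 + 2 * lay1$delta_n))
  # infeasible single-copy request names the libraries needed
  expect_error(design_assay(0.02, 1e2, ts, library_copies = 1),
               "library_copies")
})

test_that("library replication buys precision at fixed common ratio", {
  base <- geometric_layout(1, 0.5, 12)
  dv <- modulations(base)
  lib3 <- assay_layout(dilution = rep(dv, each = 3),
                       volume = rep(1, 3 * length(dv)))
  cc <- plateau_concentrations(base, 2, 1)
  # digital readout follows the 1/sqrt(k) independent-information scaling
  # the design rule assumes
  p1 <- precision_profile(base, cc, replicates = 200, mode = "digital",
                          seed = 9)
  p3 <- precision_profile(lib3, cc, replicates = 200, mode = "digital",
                          seed = 9)
  expect_equal(mean(p1$sigma) / mean(p3$sigma), sqrt(3), tolerance = 0.15)
  # the synergistic readout gains at least as much (each copy adds a Ct)
  s1 <- precision_profile(base, cc, replicates = 150, mode = "synergistic",
                          seed = 9)
  s3 <- precision_profile(lib3, cc, replicates = 150, mode = "synergistic",
                          seed = 9)
  expect_gte(mean(s1$sigma) / mean(s3$sigma),
             0.95 * mean(p1$sigma) / mean(p3$sigma))
})

test_that("classic dPCR well counts are analytic and verified by simulation", {
  cl <- classic_minimum_wells(0.1, 1e6)
  expect_gte(cl$n, 4e5)
  expect_equal(cl$sigma_check, c(0.1, 0.1), tolerance = 0.01)
  # moderate case verified by Monte-Carlo at both range ends (large enough
  # N that the delta method and saturation are not an issue)
  cl2 <- classic_minimum_wells(0.1, 10)
  set.seed(13)
  for (lam in c(cl2$lambda_minus, cl2$lambda_plus)) {
    est <- replicate(400, {
      k <- sum(rpois(cl2$n, lam) > 0)
      classic_dpcr_estimate(cl2$n, k, 1)$concentration
    })
    expect_equal(sd(est) / mean(est), 0.1, tolerance = 0.15)
  }
  # compartment demand grows near-linearly with the dynamic range (the
  # per-decade factor approaches 10 from below as the range widens)
  ns <- sapply(10^(2:5), function(om) classic_minimum_wells(0.1, om)$n)
  ratios <- ns[-1] / ns[-4]
  expect_true(all(ratios > 5 & ratios <= 10.5))
  expect_true(all(diff(ratios) > 0))
})

test_that("geometric designs scale with the log of the dynamic range", {
  ts <- get_calibration("synergistic")
  ns <- sapply(10^c(2, 4, 6), function(om)
    n_partitions(design_assay(0.4, om, ts)))
  incr <- diff(ns)
  # constant increment per added pair of decades
  expect_lt(abs(incr[2] - incr[1]), 0.25 * incr[1] + 3)
})

test_that("a fixed well budget is spent on the most precise covering design", {
  ts <- get_calibration("synergistic")
  lay <- design_for_wells(96, 1e4, ts)
  expect_equal(n_partitions(lay), 96)
  expect_lte(lay$sigma_max, 0.25)
  expect_equal(log10(lay$dyn_range), 4)
})
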