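test_that("a single negative well gives the exponential posterior", {
  lay <- assay_layout(dilution = 1, volume = 2)
  fit <- synpcr(assay_readout(lay, signal = 0), mode = "digital")
  # density dv * exp(-C dv), mean = sd = 1/dv
  expect_equal(fit$estimate, 0.5, tolerance = 1e-3)
  expect_equal(fit$sd, 0.5, tolerance = 1e-3)
  expect_equal(fit$rsd, 1, tolerance = 2e-3)
  i <- findInterval(c(0.1, 0.5, 2), fit$posterior$grid)
  g <- fit$posterior$grid[i]
  expect_equal(fit$posterior$density[i], 2 * exp(-2 * g), tolerance = 1e-3)
  expect_equal(fit$boundary, "all_negative")
})

test_that("posteriors integrate to one and match the quadrature oracle", {
  # two wells: large positive, small negative
  lay <- assay_layout(dilution = c(1, 0.01), volume = c(1, 1))
  fit <- synpcr(assay_readout(lay, signal = c(1, 0)), mode = "digital")
  orc <- oracle_posterior(c(1, 0.01), c(1, 0))
  expect_equal(fit$estimate, orc$mean, tolerance = 1e-4)
  expect_equal(fit$sd, orc$sd, tolerance = 1e-3)
  w <- c(diff(fit$posterior$grid) / 2, 0) + c(0, diff(fit$posterior$grid) / 2)
  expect_equal(sum(w * fit$posterior$density), 1, tolerance = 1e-6)
  # random small digital readouts: normalization + oracle agreement
  set.seed(14)
  for (i in 1:5) {
    dv <- 10^sort(runif(4, -3, 1), decreasing = TRUE)
    s <- rbinom(4, 1, 0.5)
    lay <- assay_layout(dilution = dv / dv[1], volume = rep(dv[1], 4))
    fit <- synpcr(assay_readout(lay, signal = s), mode = "digital")
    orc <- oracle_posterior(dv, s)
    expect_equal(fit$estimate, orc$mean, tolerance = 1e-3)
    w <- c(diff(fit$posterior$grid) / 2, 0) + c(0, diff(fit$posterior$grid) / 2)
    expect_equal(sum(w * fit$posterior$density), 1, tolerance = 1e-6)
  }
})

test_that("reference well is the latest-crossing positive, ties to the dilute", {
  lay <- assay_layout(dilution = c(1, 0.4, 0.16), volume = c(1, 1, 1))
  rd <- assay_readout(lay, signal = c(1, 1, 1), ct = c(28, 31, 25))
  expect_equal(select_reference_well(rd), "W002")
  rd1 <- assay_readout(lay, signal = c(0, 1, 0), ct = c(NA, 29, NA))
  expect_equal(select_reference_well(rd1), "W002")
  rd2 <- assay_readout(lay, signal = c(1, 1, 0), ct = c(30, 30, NA))
  expect_equal(select_reference_well(rd2), "W002")  # dv 0.4 beats dv 1
  rd3 <- assay_readout(lay, signal = c(0, 0, 0))
  expect_error(select_reference_well(rd3), "digital")
})

test_that("amplification factor is recovered exactly from noiseless Ct", {
  lay <- geometric_layout(1000, 0.25, 6)
  C <- 1
  for (q in c(2, 1.7)) {
    mbar <- C * modulations(lay)
    rd <- assay_readout(lay, signal = rep(1, 6),
                        ct = 40 - log(mbar) / log(q))
    qe <- estimate_q(rd)
    expect_equal(qe$q, q, tolerance = 1e-9)
    expect_equal(qe$se, 0, tolerance = 1e-6)
  }
})

test_that("q estimation refuses degenerate inputs with a fixed-q hint", {
  lay <- assay_layout(dilution = c(1, 0.5, 0.25), volume = c(1, 1, 1))
  rd <- assay_readout(lay, signal = c(1, 1, 0), ct = c(30, 31, NA))
  expect_error(estimate_q(rd), "fixed q.*1.9")
  # rising ct-vs-modulation slope is unphysical
  rd2 <- assay_readout(lay, signal = c(1, 1, 1), ct = c(30, 29, 28))
  expect_error(estimate_q(rd2), "slope")
})

test_that("q is recovered statistically under Ct noise", {
  lay <- geometric_layout(1e3, 0.5, 12)
  set.seed(21)
  ok <- replicate(300, {
    rd <- simulate_readout(lay, 1, q = 1.9, ct_sd = 0.25)
    qe <- tryCatch(estimate_q(rd), error = function(e) NULL)
    if (is.null(qe) || !is.finite(qe$se)) NA else abs(qe$q - 1.9) <= 3 * qe$se
  })
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("synergistic posterior reduces to the digital one when all delta_ct = 0", {
  lay <- geometric_layout(1, 0.4, 8)
  rd <- assay_readout(lay, signal = c(1, 1, 1, 0, 0, 0, 0, 0),
                      ct = c(30, 30, 30, rep(NA, 5)))
  fs <- synpcr(rd, mode = "synergistic", q = 1.9)
  fd <- synpcr(rd, mode = "digital")
  expect_identical(fs$posterior$density, fd$posterior$density)
  expect_identical(fs$estimate, fd$estimate)
  expect_equal(fs$evidence$delta_ct$k, rep(1L, 3))
})

test_that("the worked 4-well synergistic toy matches the quadrature oracle", {
  dv <- c(1, 0.1, 0.01, 0.001)
  lay <- assay_layout(dilution = dv, volume = rep(1, 4))
  rd <- assay_readout(lay, signal = c(1, 1, 0, 0), ct = c(24, 27.32, NA, NA))
  fit <- synpcr(rd, q = 2)
  # delta_ct = 3.32 cycles at q = 2 implies at least ceiling(2^3.32) = 10
  # molecules in the first well
  expect_equal(fit$evidence$reference_well, "W002")
  expect_equal(fit$evidence$delta_ct$k, c(10L, 1L))
  orc <- oracle_posterior(dv, c(1, 1, 0, 0), k = c(10, 1, 1, 1))
  expect_equal(fit$estimate, orc$mean, tolerance = 1e-3)
  expect_equal(fit$sd, orc$sd, tolerance = 2e-3)
  # the Ct information narrows the posterior
  expect_lt(fit$rsd, synpcr(rd, mode = "digital")$rsd)
})

test_that("fit object methods are coherent", {
  lay <- geometric_layout(1, 0.4, 16)
  rd <- simulate_readout(lay, 50, seed = 31)
  fit <- synpcr(rd)
  expect_s3_class(fit, "synpcr")
  expect_named(coef(fit), "concentration")
  ci <- confint(fit)
  expect_true(ci[1] < fit$estimate && fit$estimate < ci[2])
  expect_equal(unname(ci[1, ]), fit$ci95)
  expect_length(residuals(fit), 16)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "synpcr_readout")
  s <- summary(fit)
  expect_equal(s$estimate, fit$estimate)
  expect_output(print(fit), "relative sd")
})

test_that("adding a positive raises and a negative lowers the estimate", {
  set.seed(8)
  for (i in 1:6) {
    dv <- 10^sort(runif(3, -2, 1), decreasing = TRUE)
    s <- rbinom(3, 1, 0.6)
    base_lay <- assay_layout(dilution = dv / dv[1], volume = rep(dv[1], 3))
    base <- synpcr(assay_readout(base_lay, signal = s), mode = "digital")
    dv_new <- 10^runif(1, -2, 1)
    ext_lay <- assay_layout(dilution = c(dv, dv_new) / max(c(dv, dv_new)),
                            volume = rep(max(c(dv, dv_new)), 4))
    up <- synpcr(assay_readout(ext_lay, signal = c(s, 1)), mode = "digital")
    dn <- synpcr(assay_readout(ext_lay, signal = c(s, 0)), mode = "digital")
    # grids differ slightly between layouts; compare with a small allowance
    expect_gte(up$estimate, base$estimate * 0.999)
    expect_lte(dn$estimate, base$estimate * 1.001)
  }
})

test_that("classic MPN estimator matches its closed form and the posterior", {
  est <- classic_dpcr_estimate(100, 50, 1)
  expect_equal(est$concentration, log(2))
  expect_equal(est$flag, "ok")
  expect_equal(classic_dpcr_estimate(100, 0, 1)$concentration, 0)
  expect_equal(classic_dpcr_estimate(100, 0, 1)$flag, "all_negative")
  expect_equal(classic_dpcr_estimate(10, 10, 1)$flag, "saturated")
  # agrees with the digital posterior mode at mid-occupancy
  lay <- classic_layout(1, 100)
  fit <- synpcr(assay_readout(lay, signal = rep(c(1, 0), 50)), mode = "digital")
  expect_equal(fit$map, est$concentration, tolerance = 0.02)
})

test_that("synergistic fall-backs behave as documented", {
  lay <- geometric_layout(1, 0.4, 6)
  # no positive well with Ct: synergistic falls back to digital
  rd <- assay_readout(lay, signal = rep(0, 6))
  fit <- synpcr(rd, mode = "synergistic")
  expect_equal(fit$mode, "digital")
  expect_equal(fit$requested_mode, "synergistic")
  # censored positives carry no delta_ct information
  rd2 <- assay_readout(lay, signal = c(1, 1, 1, 0, 0, 0),
                       ct = c(28, 30, NA, NA, NA, NA),
                       censored = c(FALSE, FALSE, TRUE, rep(FALSE, 3)))
  fit2 <- synpcr(rd2, q = 1.9)
  expect_equal(fit2$evidence$delta_ct$k[3], 1L)
})
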