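test_that("Poisson occupancy pmf matches closed forms and sums to one", {
  expect_equal(occupancy_pmf(1, 0, 0), 1)
  expect_equal(occupancy_pmf(1, 1, 0), exp(-1))
  # direct series evaluation at lambda = 1: lambda^3 e^-lambda / 3!
  expect_equal(occupancy_pmf(0.5, 2, 3), 1^3 * exp(-1) / factorial(3))
  expect_equal(sum(occupancy_pmf(0.7, 3, 0:200)), 1, tolerance = 1e-12)
  expect_error(occupancy_pmf(1, -1, 0), "concentration")
  expect_error(occupancy_pmf(1, 1, -2), "non-negative")
  expect_error(occupancy_pmf(0, 1, 0), "dv")
})

test_that("positive-signal probability is the upper Poisson tail", {
  expect_equal(positive_probability(1, log(2), 1), 0.5)
  expect_equal(positive_probability(1, 0, 1), 0)
  expect_equal(positive_probability(1, 1, 2), 1 - 2 * exp(-1))
  expect_error(positive_probability(1, 1, 0), "m_threshold")
  # tail/pmf consistency against naive summation for m_tr <= 10, lambda <= 50
  set.seed(4)
  for (i in 1:40) {
    m_tr <- sample(1:10, 1)
    lam <- runif(1, 1e-3, 50)
    naive <- 1 - sum(dpois(0:(m_tr - 1), lam))
    expect_lt(abs(positive_probability(1, lam, m_tr) - naive), 1e-12)
  }
  # nondecreasing in concentration
  cc <- seq(0, 30, length.out = 200)
  for (m_tr in c(1L, 3L, 7L))
    expect_true(all(diff(positive_probability(0.7, cc, m_tr)) >= 0))
})

test_that("negative probability complements the positive one at threshold 1", {
  expect_equal(negative_probability(1, 1), exp(-1))
  expect_equal(negative_probability(2, 0), 1)
  set.seed(9)
  for (i in 1:20) {
    dv <- 10^runif(1, -3, 2)
    C <- 10^runif(1, -2, 3)
    expect_equal(negative_probability(dv, C) + positive_probability(dv, C, 1),
                 1, tolerance = 1e-12)
  }
})

test_that("Ct-shifted likelihood reduces to the digital sigmoid at delta_ct = 0", {
  cc <- 10^seq(-2, 2, length.out = 50)
  expect_identical(shifted_positive_probability(1, cc, 0, q = 1.7),
                   positive_probability(1, cc, 1))
  expect_identical(shifted_positive_probability(0.3, cc, 0, q = 2, m_threshold = 4L),
                   positive_probability(0.3, cc, 4L))
})

test_that("Ct-shifted likelihood uses the integer threshold ceiling(m_tr q^dct)", {
  # delta_ct = 1 at q = 2 doubles the threshold: tail above 2 at lambda = 1
  expect_equal(shifted_positive_probability(1, 1, 1, q = 2), 1 - 2 * exp(-1))
  # delta_ct = 3 at q = 2: threshold 8, brute-force tail sum at lambda = 8
  naive <- 1 - sum(dpois(0:7, 8))
  expect_equal(shifted_positive_probability(1, 8, 3, q = 2), naive,
               tolerance = 1e-12)
  # nonincreasing in delta_ct at fixed concentration
  p <- shifted_positive_probability(1, 5, seq(0, 6, by = 0.25), q = 1.9)
  expect_true(all(diff(p) <= 0))
  expect_error(shifted_positive_probability(1, 1, -0.5, q = 2), "delta_ct")
})

test_that("characteristic concentration is the half-probability point", {
  expect_equal(characteristic_concentration(1), log(2))
  expect_equal(characteristic_concentration(0.5), 2 * log(2))
  # m_tr = 3: verify against a bisection oracle on the monotone tail
  f <- function(C) positive_probability(1, C, 3L) - 0.5
  lo <- 0; hi <- 20
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(characteristic_concentration(1, 3L), (lo + hi) / 2,
               tolerance = 1e-8)
  # scales inversely with modulation for any threshold
  expect_equal(characteristic_concentration(0.2, 3L),
               characteristic_concentration(1, 3L) / 0.2)
})

test_that("Shannon entropy peaks at one bit at the characteristic concentration", {
  expect_equal(shannon_entropy(0.5), 1)
  expect_equal(shannon_entropy(0), 0)
  expect_equal(shannon_entropy(1), 0)
  p <- runif(20)
  expect_equal(shannon_entropy(p), shannon_entropy(1 - p))
  for (dv in c(0.01, 1, 37)) {
    cstar <- characteristic_concentration(dv)
    expect_equal(shannon_entropy(positive_probability(dv, cstar)), 1,
                 tolerance = 1e-9)
  }
  expect_error(shannon_entropy(1.2), "0, 1")
})

test_that("windowed log Poisson tail agrees with ppois across regimes", {
  for (k in c(2, 5, 17, 160, 4000)) {
    lam <- 10^seq(log10(k) - 3, log10(k) + 0.5, length.out = 400)
    exact <- ppois(k - 1, lam, lower.tail = FALSE, log.p = TRUE)
    fast <- synpcr:::log_pois_upper_tail(k, lam)
    keep <- exact > -600   # below that the posterior factor is dead anyway
    expect_lt(max(abs(fast[keep] - exact[keep])), 2e-3)
  }
})
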