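test_that("autocorrelation has the defining sample properties", {
  set.seed(31)
  x <- rnorm(500)
  a <- autocorrelation(x, 100)
  v <- acfValues(a)
  expect_equal(v[1], 1)
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(noiseBand(a), 1.96 / sqrt(500))
  ## strictly alternating series: C(1) ~ -1
  alt <- rep(c(1, -1), 250)
  expect_lt(acfValues(autocorrelation(alt, 10))[2], -0.99)
  ## AR(1): C(tau) ~ phi^tau over short lags
  ar1 <- as.numeric(stats::filter(rnorm(1e5), 0.9, "recursive"))
  av <- acfValues(autocorrelation(ar1, 25))
  expect_lt(max(abs(av[2:21] - 0.9^(1:20))), 0.05)
  ## degenerate inputs
  expect_error(autocorrelation(rep(0.5, 100), 10), "zero variance")
  expect_error(autocorrelation(rnorm(10), 9), "too short")
})

test_that("FFT and direct-sum ACF implementations agree", {
  set.seed(32)
  for (x in list(rnorm(257), cumsum(rnorm(1000)),
                 as.numeric(stats::filter(rnorm(5000), 0.8, "recursive")))) {
    maxLag <- min(200, length(x) - 2)
    expect_lt(max(abs(acfValues(autocorrelation(x, maxLag)) -
                        hwpopsim:::.acfDirect(x, maxLag))), 1e-10)
  }
})

test_that("exponential decay fit inverts an exact exponential", {
  a <- new("AcfResult", lags = as.numeric(0:200),
           values = exp(-0.05 * (0:200)), seriesLength = 1e4,
           noiseBand = 1.96 / sqrt(1e4))
  f <- fitExponentialDecay(a)
  expect_equal(f$rate, 0.05, tolerance = 1e-9)
  expect_equal(f$relaxationTime, 20, tolerance = 1e-7)
  expect_gt(f$goodness, 1 - 1e-12)
})

test_that("decay-rate estimation recovers the AR(1) rate within 5%", {
  ## averaged over replicate series: one length-2e5 realization carries ~7%
  ## estimator noise at the window edge
  set.seed(33)
  rates <- replicate(6, {
    x <- as.numeric(stats::filter(rnorm(2e5), 0.9, "recursive"))
    fitExponentialDecay(autocorrelation(x, 400))$rate
  })
  expect_lt(abs(mean(rates) + log(0.9)) / -log(0.9), 0.05)
})

test_that("white noise admits no exponential-decay fit", {
  set.seed(34)
  expect_error(fitExponentialDecay(autocorrelation(rnorm(5000), 500)),
               "noise-dominated|non-relaxing")
})

test_that("classification separates stable from neutral dynamics", {
  set.seed(35)
  ## AR(1): crossing within tens of lags, clean exponential -> stable
  ar1 <- as.numeric(stats::filter(rnorm(1e5), 0.9, "recursive"))
  expect_equal(classifyDynamics(autocorrelation(ar1, 2000))$label,
               "stable_exponential")
  ## random walk: correlation persists over a macroscopic lag fraction
  rw <- cumsum(rnorm(1e4))
  cw <- classifyDynamics(autocorrelation(rw, 2500))
  expect_equal(cw$label, "neutral_subexponential")

  ## the two simulator regimes at desk scale: fixed-probability mating
  ## relaxes within a few generations (stable), random mating drifts
  stable <- runTrajectory(presetConfig("fig6_acf_nonrandom", scale = 1 / 30,
                                       generations = 15000, seed = 36))
  clS <- classifyDynamics(autocorrelation(alleleFreqSeries(stable), 1500))
  expect_equal(clS$label, "stable_exponential")
  expect_lt(clS$crossingLag, 0.05 * 15001)

  neutral <- runTrajectory(presetConfig("fig5_acf_random", scale = 1 / 300,
                                        generations = 15000, seed = 36))
  clN <- classifyDynamics(autocorrelation(alleleFreqSeries(neutral), 5000))
  expect_equal(clN$label, "neutral_subexponential")
})
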