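test_that("allele frequencies follow the counting formula", {
  expect_equal(alleleFrequencies(GenotypeCounts(10, 20, 10))[["f_a"]], 0.5)
  expect_equal(alleleFrequencies(GenotypeCounts(100, 0, 0)),
               c(f_A = 1, f_a = 0))
  expect_equal(alleleFrequencies(GenotypeCounts(30, 50, 20))[["f_A"]], 0.55)
  expect_error(alleleFrequencies(GenotypeCounts(0, 0, 0)), "empty")
})

test_that("genotype counts validate on construction", {
  expect_error(GenotypeCounts(-1, 2, 3), "non-negative")
  expect_error(GenotypeCounts(1.5, 2, 3), "whole")
  expect_equal(popSize(GenotypeCounts(3, 4, 5)), 12)
  expect_equal(c(nAA(GenotypeCounts(3, 4, 5)), nAa(GenotypeCounts(3, 4, 5)),
                 naa(GenotypeCounts(3, 4, 5))), c(3, 4, 5))
})

test_that("Hardy-Weinberg expected counts are N (p^2, 2pq, q^2)", {
  expect_equal(as.numeric(hwExpectedCounts(GenotypeCounts(25, 50, 25))),
               c(25, 50, 25))
  expect_equal(as.numeric(hwExpectedCounts(GenotypeCounts(30, 50, 20))),
               c(30.25, 49.5, 20.25))
  expect_equal(as.numeric(hwExpectedCounts(GenotypeCounts(100, 0, 0))),
               c(100, 0, 0))
  ## components always sum to the observed total
  set.seed(101)
  for (i in 1:50) {
    k <- GenotypeCounts(sample(0:500, 3, replace = TRUE))
    if (popSize(k) == 0) next
    expect_equal(sum(hwExpectedCounts(k)), popSize(k),
                 tolerance = 1e-9)
  }
})

test_that("chi-square statistic matches the independent oracle and its bounds", {
  expect_equal(unname(hwChiSquare(GenotypeCounts(25, 50, 25))$statistic), 0)
  ## all-homozygote extreme saturates the finite-population bound chi2 = N
  expect_equal(unname(hwChiSquare(GenotypeCounts(50, 0, 50))$statistic), 100)
  ## frozen from an independent oracle (scipy): 0.0102030405
  expect_equal(unname(hwChiSquare(GenotypeCounts(30, 50, 20))$statistic),
               0.0102030405, tolerance = 1e-7)
  expect_equal(unname(hwChiSquare(GenotypeCounts(0, 0, 77))$statistic), 0)
  expect_equal(unname(hwChiSquare(GenotypeCounts(30, 50, 20))$parameter), 1)

  ## 0 <= chi2 <= N, and scaling counts by an integer factor scales chi2
  set.seed(202)
  for (i in 1:100) {
    k <- sample(0:300, 3, replace = TRUE)
    if (sum(k) == 0) next
    s <- unname(hwChiSquare(GenotypeCounts(k))$statistic)
    expect_gte(s, 0)
    expect_lte(s, sum(k) * (1 + 1e-9))  # bound holds up to float round-off
    lambda <- sample(2:5, 1)
    expect_equal(unname(hwChiSquare(GenotypeCounts(lambda * k))$statistic),
                 lambda * s, tolerance = 1e-9)
  }
})

test_that("chi-square p-values and critical values invert each other", {
  expect_equal(chiSquarePValue(0, 1), 1)
  expect_equal(chiSquarePValue(3.841459, 1), 0.05, tolerance = 1e-6)
  ## chi2_1 is the square of a standard normal
  for (x in c(4, 9, 16))
    expect_equal(chiSquarePValue(x, 1), 2 * pnorm(-sqrt(x)),
                 tolerance = 1e-12)
  expect_equal(chiSquareCriticalValue(0.05, 1), 3.841459, tolerance = 1e-6)
  for (a in c(0.001, 0.05, 0.5, 0.99)) for (df in c(1, 2, 5))
    expect_equal(chiSquarePValue(chiSquareCriticalValue(a, df), df), a,
                 tolerance = 1e-9)
  ## p-value decreases as the statistic grows
  expect_true(all(diff(chiSquarePValue(seq(0, 20, by = 0.5), 1)) < 0))
  expect_error(chiSquarePValue(-1, 1), "non-negative")
  expect_error(chiSquareCriticalValue(0, 1), "strictly between")
  expect_error(chiSquareCriticalValue(1.2, 1), "strictly between")
})

test_that("chi-square of HW-multinomial populations follows the canonical law", {
  ## counts drawn multinomial(N; p^2, 2pq, q^2): the tail fraction above the
  ## 0.05 critical value must sit within 3 Monte-Carlo SE of 0.05
  set.seed(303)
  N <- 1e4
  p <- 0.3
  L <- 2000
  draws <- rmultinom(L, N, c(p^2, 2 * p * (1 - p), (1 - p)^2))
  stats <- apply(draws, 2, function(k)
    unname(hwChiSquare(GenotypeCounts(k))$statistic))
  frac <- mean(stats > chiSquareCriticalValue(0.05, 1))
  se <- sqrt(0.05 * 0.95 / L)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("subsampling is multivariate hypergeometric", {
  k <- GenotypeCounts(500, 1000, 500)
  expect_equal(subsampleCounts(k, popSize(k))@counts, k@counts)
  expect_equal(popSize(subsampleCounts(k, 0)), 0)
  expect_error(subsampleCounts(k, 5000), "more individuals")
  set.seed(404)
  reps <- t(replicate(2000, subsampleCounts(k, 50)@counts))
  expect_true(all(rowSums(reps) == 50))
  ## component means n * class fraction, 4 sigma band on the mean
  expMean <- 50 * c(0.25, 0.5, 0.25)
  sds <- sqrt(50 * c(.25, .5, .25) * (1 - c(.25, .5, .25)) * (1950 / 1999))
  for (j in 1:3)
    expect_lt(abs(mean(reps[, j]) - expMean[j]), 4 * sds[j] / sqrt(2000))
})
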