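test_that("reproductive pool draws respect composition and errors", {
  allAA <- GenotypeCounts(50, 0, 0)
  expect_equal(drawReproductivePool(allAA, 10), rep("AA", 10))
  ## drawing the whole population under random mating is a permutation
  k <- GenotypeCounts(5, 7, 4)
  set.seed(1)
  pool <- drawReproductivePool(k, 16, randomMating())
  expect_equal(as.vector(table(factor(pool, c("AA", "Aa", "aa")))),
               c(5, 7, 4))
  expect_error(drawReproductivePool(k, 15), "even")
  expect_error(drawReproductivePool(k, 18), "larger than the population")

  ## fixed-class probabilities: pool tallies track the configured probs
  big <- GenotypeCounts(4e4, 4e4, 4e4)
  set.seed(2)
  pool <- drawReproductivePool(big, 2e4, fixedClassMating(c(0.23, 0.54, 0.23)))
  tal <- table(factor(pool, c("AA", "Aa", "aa"))) / 2e4
  for (j in 1:3)
    expect_lt(abs(tal[j] - c(0.23, 0.54, 0.23)[j]),
              4 * sqrt(0.54 * 0.46 / 2e4))
})

test_that("fixed-probability draws renormalize exactly when a class empties", {
  ## a tiny AA class with a large AA probability must empty and renormalize
  k <- GenotypeCounts(5, 100, 100)
  probs <- c(0.9, 0.05, 0.05)
  set.seed(3)
  for (i in 1:20) {
    pool <- drawReproductivePool(k, 50, fixedClassMating(probs))
    expect_length(pool, 50)
    expect_lte(sum(pool == "AA"), 5)
  }
  ## exact sequential law: compare against brute-force enumeration over all
  ## ordered draws (renormalized at exhaustion), TV distance on couple types
  exact <- oraclePoolDist(c(2, 0, 2), 4, probs = c(0.7, 0, 0.3))
  set.seed(4)
  keys <- replicate(20000, {
    pool <- drawReproductivePool(GenotypeCounts(2, 0, 2), 4,
                                 fixedClassMating(c(0.7, 0, 0.3)))
    oracleCoupleKey(match(pool, c("AA", "Aa", "aa")))
  })
  expect_lt(oracleTV(exact, table(keys)), 0.01)
})

test_that("pairing tallies consecutive pool members", {
  expect_equal(unname(pairCouples(c("aa", "aa"))),
               c(0, 0, 0, 0, 0, 1))
  expect_equal(unname(pairCouples(c("AA", "aa", "AA", "aa"))),
               c(0, 0, 2, 0, 0, 0))
  expect_error(pairCouples(c("AA", "Aa", "aa")), "even")
  expect_error(pairCouples(c("AA", "XX")), "labels")

  ## random pools from (2 AA, 2 aa): both couples mixed with probability
  ## 2/3, two homozygote couples with probability 1/3 (all 3 matchings of 4
  ## individuals are equally likely)
  set.seed(5)
  mixed <- replicate(30000, {
    pool <- drawReproductivePool(GenotypeCounts(2, 0, 2), 4, randomMating())
    cc <- pairCouples(pool)
    cc[["AAxaa"]] == 2
  })
  expect_lt(abs(mean(mixed) - 2 / 3), 4 * sqrt(2 / 9 / 30000))
})

test_that("reproduction is Mendelian with the configured family sizes", {
  det4 <- ReproductionSpec("deterministic", 4)
  cc <- setNames(numeric(6),
                 c("AAxAA", "AAxAa", "AAxaa", "AaxAa", "Aaxaa", "aaxaa"))
  cc["AAxaa"] <- 5
  expect_equal(reproduceCouples(cc, det4)@counts,
               c(AA = 0, Aa = 20, aa = 0))
  cc[] <- 0; cc["aaxaa"] <- 3
  expect_equal(reproduceCouples(cc, ReproductionSpec("deterministic", 2))@counts,
               c(AA = 0, Aa = 0, aa = 6))
  ## heterozygote crosses segregate 1/4 : 1/2 : 1/4
  cc[] <- 0; cc["AaxAa"] <- 1000
  set.seed(6)
  off <- reproduceCouples(cc, det4)@counts
  expect_equal(sum(off), 4000)
  sds <- sqrt(4000 * c(.25, .5, .25) * (1 - c(.25, .5, .25)))
  for (j in 1:3)
    expect_lt(abs(off[j] - 4000 * c(.25, .5, .25)[j]), 4.5 * sds[j])

  ## stochastic family sizes hit the configured mean
  spec <- ReproductionSpec("stochastic", countProbs = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(meanOffspring(spec), 3)
  cc[] <- 0; cc["aaxaa"] <- 4000
  set.seed(7)
  tot <- popSize(reproduceCouples(cc, spec))
  expect_lt(abs(tot - 12000), 4.5 * sqrt(4000 * 1))  # per-couple var = 1
})

test_that("culling keeps a uniform random subset at capacity", {
  k <- GenotypeCounts(10, 20, 10)
  expect_equal(cullToCapacity(k, 100)@counts, k@counts)
  expect_equal(popSize(cullToCapacity(k, 0)), 0)
  set.seed(8)
  surv <- t(replicate(1000, cullToCapacity(GenotypeCounts(4000, 8000, 4000),
                                           4000)@counts))
  expect_true(all(rowSums(surv) == 4000))
  expMean <- c(1000, 2000, 1000)
  for (j in 1:3)
    expect_lt(abs(mean(surv[, j]) - expMean[j]),
              4 * sqrt(4000 * .25 * .75) / sqrt(1000))
})

test_that("one generation matches the brute-force enumeration oracle", {
  ## population (1 AA, 1 Aa, 1 aa), pool of 2, 2 offspring per couple:
  ## the exact outcome distribution over offspring triples is enumerable
  exact <- oracleGenerationDist(c(1, 1, 1), 2, kids = 2)
  cfg <- SimulationConfig(GenotypeCounts(1, 1, 1), capacity = 10,
                          reproducingCount = 2,
                          reproduction = ReproductionSpec("deterministic", 2),
                          generations = 1)
  set.seed(9)
  obs <- replicate(1e5, paste(advanceGeneration(GenotypeCounts(1, 1, 1),
                                                cfg)@counts, collapse = ","))
  expect_lt(oracleTV(exact, table(obs)), 0.01)
})

test_that("monomorphic states are absorbing and totals are conserved", {
  cfg <- SimulationConfig(GenotypeCounts(0, 0, 40), capacity = 500,
                          reproducingFraction = 0.6, generations = 30,
                          seed = 10)
  d <- as.data.frame(runTrajectory(cfg))
  expect_true(all(d$f_a == 1))
  expect_true(all(d$n_AA == 0 & d$n_Aa == 0))
  expect_true(all(d$chi2 == 0))
  ## growth then capacity: total = min(offspring, capacity), never negative
  tot <- d$n_AA + d$n_Aa + d$n_aa
  expect_true(all(tot <= 500) && all(tot > 0))
  expect_true(all(tail(tot, 10) == 500))
})

test_that("random mating leaves the allele frequency a martingale", {
  k0 <- GenotypeCounts(300, 400, 300)
  f0 <- alleleFrequencies(k0)[["f_a"]]
  cfg <- SimulationConfig(k0, capacity = 1000, reproducingCount = 600,
                          generations = 1)
  set.seed(11)
  f1 <- replicate(1e4,
    alleleFrequencies(advanceGeneration(k0, cfg))[["f_a"]])
  z <- (mean(f1) - f0) / (sd(f1) / sqrt(length(f1)))
  expect_lt(abs(z), 3)
})

test_that("fixed-probability mating drives f_A to P_AA + P_Aa/2", {
  probs <- c(0.5, 0.3, 0.2)   # asymmetric on purpose -> f_A = 0.65
  k0 <- GenotypeCounts(4e4, 4e4, 4e4)
  cfg <- SimulationConfig(k0, capacity = 1.2e5, reproducingCount = 6e4,
                          mating = fixedClassMating(probs), generations = 1)
  set.seed(12)
  fA <- replicate(30, alleleFrequencies(advanceGeneration(k0, cfg))[["f_A"]])
  expect_lt(abs(mean(fA) - 0.65), 4 * sd(fA) / sqrt(30))
})

test_that("exact and large-N samplers agree where they overlap", {
  k0 <- GenotypeCounts(3000, 1500, 1500)
  mk <- function(thr) SimulationConfig(k0, capacity = 6000,
                                       reproducingCount = 3600,
                                       generations = 1, poolThreshold = thr)
  set.seed(13)
  fExact <- replicate(600,
    alleleFrequencies(advanceGeneration(k0, mk(1e5)))[["f_a"]])
  fApprox <- replicate(600,
    alleleFrequencies(advanceGeneration(k0, mk(1)))[["f_a"]])
  ## identical one-step mean (martingale) and comparable spread
  tt <- (mean(fExact) - mean(fApprox)) /
    sqrt(var(fExact) / 600 + var(fApprox) / 600)
  expect_lt(abs(tt), 4)
  expect_lt(sd(fApprox) / sd(fExact), 2)
  expect_gt(sd(fApprox) / sd(fExact), 0.5)
})

test_that("trajectories are deterministic given a seed and record bottlenecks", {
  cfg <- presetConfig("fig3_bottleneck_random", scale = 1 / 3000,
                      generations = 60, seed = 14)
  d1 <- as.data.frame(runTrajectory(cfg))
  d2 <- as.data.frame(runTrajectory(cfg))
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 61)
  ## per-record internal consistency: frequencies and chi2 recomputable
  for (i in sample(seq_len(nrow(d1)), 10)) {
    k <- GenotypeCounts(d1$n_AA[i], d1$n_Aa[i], d1$n_aa[i])
    expect_equal(alleleFrequencies(k)[["f_A"]], d1$f_A[i], tolerance = 1e-12)
    expect_equal(unname(hwChiSquare(k)$statistic), d1$chi2[i],
                 tolerance = 1e-9)
  }

  ## a bottleneck replaces the population after the scheduled generation:
  ## resetting a monomorphic-aa run to all-AA flips f_a to 0 from the next
  ## record onward
  cfg2 <- SimulationConfig(GenotypeCounts(0, 0, 100), capacity = 200,
                           reproducingFraction = 0.6, generations = 6,
                           bottlenecks = list(
                             BottleneckEvent(3, GenotypeCounts(100, 0, 0))),
                           seed = 15)
  d <- as.data.frame(runTrajectory(cfg2))
  expect_true(all(d$f_a[d$generation <= 3] == 1))
  expect_true(all(d$f_a[d$generation >= 4] == 0))
})

test_that("undersized populations abort with the generation index", {
  cfg <- SimulationConfig(GenotypeCounts(2, 0, 0), capacity = 100,
                          reproducingCount = 50, generations = 5,
                          reproduction = ReproductionSpec("deterministic", 1),
                          seed = 16)
  expect_error(runTrajectory(cfg), "generation 1")
})

test_that("configuration validity catches inconsistent parameters", {
  expect_error(SimulationConfig(GenotypeCounts(1, 1, 1), capacity = 10,
                                reproducingFraction = 1.2, generations = 1),
               "reproducingFraction")
  expect_error(SimulationConfig(GenotypeCounts(1, 1, 1), capacity = 10,
                                reproducingCount = 3, generations = 1),
               "even")
  expect_error(SimulationConfig(GenotypeCounts(1, 1, 1), capacity = 10,
                                generations = 1),
               "exactly one")
  expect_error(SimulationConfig(GenotypeCounts(1, 1, 1), capacity = 10,
                                reproducingCount = 2, generations = 1,
                                bottlenecks = list(
                                  BottleneckEvent(5, GenotypeCounts(1, 1, 1)))),
               "beyond the simulated horizon")
  expect_error(MatingScheme("fixed", c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(ReproductionSpec("deterministic", 5), "1, 2, 3, 4")
})
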