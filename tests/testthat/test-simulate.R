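# Poisson SFS sampling, rate scalings, dataset simulation, power grids.

test_that("Poisson SFS sampling is seeded, nonnegative and mean-correct", {
  expect_equal(sampleSFSPoisson(c(0, 0, 0)), c(0, 0, 0))
  a <- sampleSFSPoisson(c(3, 2, 1), seed = 99)
  b <- sampleSFSPoisson(c(3, 2, 1), seed = 99)
  expect_identical(a, b)
  expect_error(sampleSFSPoisson(c(1, -1)), "non-negative")
  set.seed(2)
  m <- c(5, 2, 0.5)
  draws <- t(replicate(10000, sampleSFSPoisson(m)))
  se <- sqrt(m / 10000)
  expect_true(all(abs(colMeans(draws) - m) <= 3 * se + 1e-9))
})

test_that("theta and rho scalings follow the reduction factors", {
  s <- scaledRates(0.5, 0.001, 0.001)
  expect_equal(s$thetaX / s$thetaA, 0.75)
  expect_equal(s$rhoX / s$rhoA, 0.5)
  s2 <- scaledRates(0.2, 1, 1)
  expect_equal(s2$thetaX / s2$thetaA, qRatio(0.2))
  expect_equal(s2$thetaX / s2$thetaA, 9 / (8 * 1.8))
  ## female-limited X recombination factor 2p/(1+p) -> 1 as p -> 1
  s3 <- scaledRates(0.999, 1, 1)
  expect_equal(s3$rhoX / (reductionFactorX(0.999) * 1), 2 * 0.999 / 1.999)
})

test_that("simulated site totals follow the no-bias expectation ratio", {
  set.seed(41)
  cfg <- experimentConfig("constant", p = 0.5, nLoci = 300L)
  SX <- SA <- numeric(40)
  for (i in 1:40) {
    d <- simulateDataset(cfg)
    SA[i] <- sum(d$lociA); SX[i] <- sum(d$lociX)
  }
  HA <- expectedSFSConstant(cfg$nA)@sumF
  HX <- expectedSFSConstant(cfg$nX)@sumF
  expect_equal(mean(SX) / mean(SA), 0.75 * HX / HA, tolerance = 0.05)
})

test_that("dataset simulation is deterministic under a seed", {
  cfg <- experimentConfig("constant", p = 0.4, nLoci = 20L, seed = 7)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1$lociA, d2$lociA)
  expect_identical(d1$lociX, d2$lociX)
})

test_that("linked and unlinked modes share the same mean SFS", {
  set.seed(19)
  census <- demography(nu = c(1, 6), dur = c(Inf, 0.05), Nref = 5000)
  cfgU <- simConfig(census, p = 0.3, nA = 12, nX = 12, L = 2e4,
                    nLoci = 800, mu = 1e-6)
  cfgL <- utils::modifyList(cfgU, list(linked = TRUE))
  class(cfgL) <- "simConfig"
  dU <- simulateDataset(cfgU)
  dL <- simulateDataset(cfgL)
  ## per-entry agreement within Monte-Carlo error (linkage changes variance,
  ## not the mean)
  seA <- sqrt(apply(dL$lociA, 2, var) / nrow(dL$lociA) +
              apply(dU$lociA, 2, var) / nrow(dU$lociA))
  diffA <- abs(colMeans(dL$lociA) - colMeans(dU$lociA))
  expect_true(all(diffA <= 4 * seA + 1e-9))
  ## linked mode inflates the variance of per-locus totals
  expect_gt(var(rowSums(dL$lociA)), var(rowSums(dU$lociA)))
})

test_that("unlinked simulated means match the engine for every preset", {
  set.seed(57)
  for (ex in c("constant", "bottleneck")) {
    cfg <- experimentConfig(ex, p = 0.5, nLoci = 2000L,
                            nA = 20L, nX = 20L, L = 2000)
    d <- simulateDataset(cfg)
    mn <- colMeans(d$lociA)
    se <- apply(d$lociA, 2, sd) / sqrt(nrow(d$lociA))
    expect_true(all(abs(mn - d$meansA) <= 3.5 * se + 1e-9))
  }
})

test_that("power grid tables carry one row per cell and replicate", {
  set.seed(71)
  ## larger datasets so the male-bias cell sits in the high-power regime
  df <- runPowerGrid("constant", pGrid = c(0.2, 0.5), reps = 3,
                     nLoci = 5000L)
  expect_equal(nrow(df), 6L)
  expect_true(all(c("p1", "p2", "rep", "lambda0", "reject0", "pTilde",
                    "pPi") %in% names(df)))
  ## strong male bias is rejected far more often than the null
  pow <- tapply(df$reject0, df$p1, mean)
  expect_gte(pow[["0.2"]], pow[["0.5"]])
  ## single-replicate cells are valid
  df1 <- runPowerGrid("constant", pGrid = 0.5, reps = 1)
  expect_equal(nrow(df1), 1L)
})
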