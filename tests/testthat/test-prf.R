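# Poisson random field likelihoods and theta MLEs.

test_that("poisson log-likelihood matches hand arithmetic and the MLE property", {
  expect_equal(poissonLogLik(c(1, 0), c(1, 0.5)), -1.5)
  ## rescaling the expected vector is maximized when observed == expected
  obs <- c(4, 2, 1)
  f <- function(c) poissonLogLik(obs, c * obs)
  expect_gt(f(1), f(0.8))
  expect_gt(f(1), f(1.25))
  ## masked classes are excluded
  s <- spectrumData(c(4, 2, 1), n = 4, mask = c(FALSE, TRUE, FALSE))
  expect_equal(poissonLogLik(s, c(4, 99, 1)),
               poissonLogLik(c(4, 1), c(4, 1)))
  expect_error(poissonLogLik(c(1, 1), c(1, 0)), "non-positive expected")
})

test_that("likelihood at the truth beats an inflated rate in most draws", {
  set.seed(42)
  lam <- c(20, 12, 8, 4)
  wins <- mean(replicate(1000, {
    x <- rpois(4, lam)
    poissonLogLik(x, lam) > poissonLogLik(x, 2 * lam)
  }))
  expect_gte(wins, 0.95)
})

test_that("theta MLE is S over the Watterson denominator and is unbiased", {
  s <- spectrumData(c(5, 3, 1, 1), n = 5)
  expect_equal(thetaMLE(s), 10 / (1 + 1 / 2 + 1 / 3 + 1 / 4))
  expect_equal(thetaMLE(spectrumData(c(0, 0, 0, 0), n = 5)), 0)
  set.seed(8)
  n <- 20; theta <- 10
  lam <- theta * expectedSFSConstant(n)@F
  est <- replicate(1000, thetaMLE(spectrumData(rpois(n - 1, lam), n)))
  expect_lt(abs(mean(est) - theta), 2 * sd(est) / sqrt(1000))
})

test_that("joint null theta MLE reproduces the observed site totals", {
  nA <- 8; nX <- 6; LA <- 1000; LX <- 1000
  sA <- spectrumData(c(40, 15, 9, 5, 3, 2, 1), n = nA, L = LA)
  sX <- spectrumData(c(12, 5, 4, 2, 2), n = nX, L = LX)
  th0 <- thetaNullJoint(sA, sX)
  HA <- expectedSFSConstant(nA)@sumF; HX <- expectedSFSConstant(nX)@sumF
  ## plugging theta back recovers E[S_A] + E[S_X] = S_A + S_X
  expect_equal(th0 * (LA * HA + 0.75 * LX * HX), segSites(sA) + segSites(sX))
  expect_error(thetaNullJoint(sA, NULL), "both")
})

test_that("alternative joint theta equals the null at p = 0.5 and recovers truth", {
  nA <- 8; nX <- 6
  sA <- spectrumData(c(40, 15, 9, 5, 3, 2, 1), n = nA, L = 1000)
  sX <- spectrumData(c(12, 5, 4, 2, 2), n = nX, L = 1000)
  expect_equal(thetaAltJoint(sA, sX, p = 0.5), thetaNullJoint(sA, sX))
  ## continuity in p
  ps <- seq(0.1, 0.9, by = 0.01)
  th <- vapply(ps, function(p) thetaAltJoint(sA, sX, p), numeric(1))
  expect_true(all(is.finite(th)))
  expect_lt(max(abs(diff(th))), 0.1 * max(th))
  ## simulation recovery at p = 0.2
  set.seed(12)
  theta <- 0.002; p <- 0.2; L <- 5e4
  lamA <- reductionFactorA(p) * theta * L * expectedSFSConstant(20)@F
  lamX <- reductionFactorX(p) * theta * L * expectedSFSConstant(20)@F
  est <- replicate(300, {
    a <- spectrumData(rpois(19, lamA), 20, L = L)
    x <- spectrumData(rpois(19, lamX), 20, L = L, chromClass = "X")
    thetaAltJoint(a, x, p = p)
  })
  expect_lt(abs(mean(est) - theta), 3 * sd(est) / sqrt(300))
})

test_that("profile likelihood over p peaks at the closed-form estimate", {
  set.seed(21)
  theta <- 0.003; p0 <- 0.35; L <- 1e5; n <- 30
  F <- expectedSFSConstant(n)@F
  sA <- spectrumData(rpois(n - 1, reductionFactorA(p0) * theta * L * F),
                     n, L = L)
  sX <- spectrumData(rpois(n - 1, reductionFactorX(p0) * theta * L * F),
                     n, L = L, chromClass = "X")
  ll <- function(p) {
    th <- thetaAltJoint(sA, sX, p)
    poissonLogLik(sA, th * reductionFactorA(p) * L * F) +
      poissonLogLik(sX, th * reductionFactorX(p) * L * F)
  }
  pGrid <- seq(0.05, 0.95, by = 0.001)
  pHat <- pGrid[which.max(vapply(pGrid, ll, numeric(1)))]
  expect_equal(pHat, pTildeConstant(sA, sX), tolerance = 2e-3)
})
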