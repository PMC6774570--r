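# Fitting, nested LRTs, bootstraps.

test_that("noiseless two-epoch spectra are recovered within 5 percent", {
  census <- presetDemography("growth")
  dA <- scaleDemographyBySex(census, 0.5, "autosome")
  n <- 100; mu <- 1.5e-8; L <- 5e6
  sA <- spectrumData(4 * dA@Nref * mu * L * expectedSFS(dA, n)@F, n,
                     L = L, mu = mu)
  fit <- fitAutosomal(sA, "growth")
  expect_true(fit@converged)
  expect_equal(unname(fit@trace$par[["nu"]]), 55, tolerance = 0.05)
  expect_equal(unname(fit@trace$par[["T"]]), 205 / 15400, tolerance = 0.05)
  expect_equal(fit@theta, 4 * dA@Nref * mu, tolerance = 0.01)
  expect_equal(ancestralSize(fit@model), dA@Nref, tolerance = 0.01)
})

test_that("constant-size theta is recovered without bias across draws", {
  set.seed(31)
  n <- 20; theta <- 10; F <- expectedSFSConstant(n)@F
  est <- replicate(400, {
    s <- spectrumData(rpois(n - 1, theta * F), n)
    fitAutosomal(s, "constant")@theta
  })
  expect_lt(abs(mean(est) - theta), 3 * sd(est) / sqrt(400))
})

test_that("empty spectra are rejected", {
  expect_error(fitAutosomal(spectrumData(rep(0, 9), 10), "growth"), "empty")
})

test_that("nested X model ladder is ordered and recovers a constant bias", {
  set.seed(17)
  cfg <- experimentConfig("expansion", p = 0.2, nA = 100L, nX = 100L,
                          nLoci = 400L)
  d <- simulateDataset(cfg)
  fa <- fitAutosomal(d$sfsA, "growth", init = c(nu = 55, T = 205 / 15400),
                     gridPoints = 0)
  f0 <- fitXConstrained(d$sfsX, fa, "M0")
  f1 <- fitXConstrained(d$sfsX, fa, "M1")
  fT <- fitXConstrained(d$sfsX, fa, "MT")
  ## likelihood ordering of the nested surfaces
  expect_lte(f0@loglik, f1@loglik + 1e-6)
  expect_lte(f1@loglik, fT@loglik + 1e-6)
  ## constant male bias recovered
  expect_lt(abs(f1@pEstimates[1] - 0.2), 0.08)
  ## M0 has no free parameters and p fixed at 0.5
  expect_equal(f0@pEstimates, c(0.5, 0.5))
  t0 <- lrtSexBias(f0, f1)
  expect_gte(t0@lambda[[1]], 0)
  expect_true(t0@reject)  # strong bias, many sites
  expect_error(lrtSexBias(f1, f0), "not nested")
})

test_that("identical models give a zero LRT statistic and acceptance", {
  set.seed(5)
  cfg <- experimentConfig("constant", p = 0.5, nLoci = 50L)
  d <- simulateDataset(cfg)
  tst <- lrtConstantSize(d$sfsA, d$sfsX)
  expect_gte(tst@lambda[[1]], 0)
  f <- new("FitResult", model = demography(1, Inf), theta = 1,
           loglik = -10, converged = TRUE,
           trace = list(level = "M0", llA = -4, nFree = 0L), level = "M0",
           pEstimates = 0.5)
  g <- new("FitResult", model = demography(1, Inf), theta = 1,
           loglik = -10, converged = TRUE,
           trace = list(level = "M1", llA = -4, nFree = 1L), level = "M1",
           pEstimates = 0.5)
  tid <- lrtSexBias(f, g)
  expect_equal(tid@lambda[[1]], 0)
  expect_false(tid@reject)
})

test_that("constant-size LRT type-I error sits near the nominal level", {
  set.seed(23)
  cfg <- experimentConfig("constant", p = 0.5)
  lam <- replicate(400, {
    d <- simulateDataset(cfg)
    lrtConstantSize(d$sfsA, d$sfsX)@lambda[[1]]
  })
  rate <- mean(lam > qchisq(0.95, 1))
  ## binomial 99% band around 0.05 at 400 reps
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 400))
})

test_that("Lambda is invariant to a common rescaling of lengths and theta", {
  set.seed(9)
  n <- 40; F <- expectedSFSConstant(n)@F
  cA <- rpois(n - 1, 0.001 * 5e5 * F)
  cX <- rpois(n - 1, 0.00075 * 5e5 * F)
  l1 <- lrtConstantSize(spectrumData(cA, n, L = 5e5),
                        spectrumData(cX, n, L = 5e5, chromClass = "X"))
  l2 <- lrtConstantSize(spectrumData(cA, n, L = 5e6),
                        spectrumData(cX, n, L = 5e6, chromClass = "X"))
  expect_equal(l1@lambda[[1]], l2@lambda[[1]], tolerance = 1e-9)
})

test_that("parametric bootstrap returns CIs that cover a null p of 0.5", {
  set.seed(77)
  cfg <- experimentConfig("expansion", p = 0.5, nA = 60L, nX = 60L,
                          nLoci = 200L)
  d <- simulateDataset(cfg)
  ## at this reduced data size the growth magnitude sits on a flat ridge;
  ## the p inference this test targets is unaffected
  suppressWarnings({
    fa <- fitAutosomal(d$sfsA, "growth", init = c(nu = 55, T = 205 / 15400),
                       gridPoints = 0, maxRestarts = 1)
    f1 <- fitXConstrained(d$sfsX, fa, "M1")
    bs <- parametricBootstrap(fa, f1, d$sfsA, d$sfsX, nReps = 10)
  })
  expect_equal(bs$nFailed, 0L)
  ci <- bs$ci[, "p1"]
  expect_lt(ci[1], 0.58)
  expect_gt(ci[2], 0.42)
  expect_true(all(bs$critical >= 0))
  expect_error(parametricBootstrap(fa, f1, d$sfsA, d$sfsX, nReps = 0),
               "nReps")
})

test_that("block bootstrap keeps blocks intact and calibrates iid SEs", {
  set.seed(55)
  nLoci <- 100; n <- 10
  lamA <- 2 * expectedSFSConstant(n)@F
  lamX <- 1.5 * expectedSFSConstant(n)@F
  coords <- data.frame(chrom = "1", pos = (seq_len(nLoci) - 1) * 1e6 + 1)
  statQ <- function(a, x) sum(x) / sum(a)
  genome <- function() {
    list(A = matrix(rpois(nLoci * (n - 1), rep(lamA, each = nLoci)), nLoci),
         X = matrix(rpois(nLoci * (n - 1), rep(lamX, each = nLoci)), nLoci))
  }
  g <- genome()
  bb <- blockBootstrap(g$A, g$X, coords, coords, statQ, iters = 120)
  ## empirical SD across independent genomes
  emp <- sd(replicate(150, { h <- genome(); statQ(colSums(h$A), colSums(h$X)) }))
  expect_lt(abs(bb$se - emp) / emp, 0.30)
  expect_error(blockBootstrap(g$A[1:2, ], g$X, coords[1:2, ], coords, statQ,
                              blockSize = 1e9), "2 blocks")
})
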