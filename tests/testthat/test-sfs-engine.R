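# Expected-SFS engine, folding and projection.

test_that("constant-size density is the harmonic sequence", {
  d <- expectedSFSConstant(4)
  expect_equal(d@F, c(1, 1 / 2, 1 / 3))
  expect_equal(d@sumF, sum(1 / (1:3)))
  expect_equal(expectedSFSConstant(2)@F, 1)
  ## expected segregating sites theta * H_{n-1}
  expect_equal(100 * expectedSFSConstant(10)@sumF, 282.896825, tolerance = 1e-6)
  expect_error(expectedSFSConstant(1), "n must")
})

test_that("multi-epoch engine reduces to 1/i when all sizes are 1", {
  dem <- demography(nu = c(1, 1, 1), dur = c(Inf, 0.3, 0.17))
  F <- expectedSFS(dem, 20)@F
  expect_equal(F * (1:19), rep(1, 19), tolerance = 1e-3)
  ## single ancestral epoch is exact
  F1 <- expectedSFS(demography(1, Inf), 20)@F
  expect_equal(F1 * (1:19), rep(1, 19), tolerance = 1e-12)
})

test_that("recent growth skews the spectrum towards singletons", {
  dem <- demography(nu = c(1, 55), dur = c(Inf, 205), Nref = 7700,
                    units = "generations")
  F <- expectedSFS(dem, 500)@F
  F0 <- expectedSFSConstant(500)@F
  expect_gt(F[1] / sum(F), F0[1] / sum(F0))
})

test_that("engine agrees with the coalescent-mean oracle per entry", {
  ## the tree sampler is an independent Monte-Carlo route to the same
  ## expectation (simulated genealogies vs lineage-count integration)
  set.seed(101)
  n <- 12; mu <- 1e-6; L <- 2e4; reps <- 4000
  dems <- list(
    constant = demography(1, Inf, Nref = 4000),
    growth = demography(nu = c(1, 10), dur = c(Inf, 0.05), Nref = 4000),
    bottleneck = demography(nu = c(1, 0.1, 5), dur = c(Inf, 0.06, 0.03),
                            Nref = 4000)
  )
  for (dem in dems) {
    sim <- simulateCoalescentSFS(dem, n, mu, L, reps)
    mn <- colMeans(sim)
    se <- apply(sim, 2, sd) / sqrt(reps)
    expct <- 4 * dem@Nref * mu * L * expectedSFS(dem, n)@F
    z <- (mn - expct) / se
    ## per-entry band widened to 4 SE for a family-wise check over
    ## 3 x (n-1) entries; a systematic shift is caught by the mean-z check
    expect_lt(max(abs(z)), 4)
    expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  }
})

test_that("exponential epochs are handled and match a fine staircase", {
  demE <- demography(nu = c(1, 8), dur = c(Inf, 0.1),
                     change = c("instantaneous", "exponential"))
  ## manual staircase approximation of the same exponential trajectory
  ns <- 64
  u <- (seq_len(ns) - 0.5) / ns * 0.1
  nuU <- 8 * (1 / 8)^(u / 0.1)
  demS <- demography(nu = c(1, rev(nuU)), dur = c(Inf, rep(0.1 / ns, ns)))
  expect_equal(expectedSFS(demE, 25)@F, expectedSFS(demS, 25)@F,
               tolerance = 1e-3)
})

test_that("folding combines mirror classes and conserves totals", {
  s <- spectrumData(c(3, 2, 1), n = 4)
  f <- foldSFS(s)
  expect_equal(sfsCounts(f), c(4, 2))
  expect_equal(segSites(f), segSites(s))
  s5 <- spectrumData(c(4, 3, 2, 1), n = 5)
  expect_equal(sfsCounts(foldSFS(s5)), c(5, 5))
  ## symmetric spectrum doubles the outer class
  sym <- spectrumData(c(7, 1, 7), n = 4)
  expect_equal(sfsCounts(foldSFS(sym))[1], 14)
  expect_error(foldSFS(foldSFS(s)), "already folded")
  ## fold-then-sum equals sum-then-fold
  a <- spectrumData(c(1, 2, 3, 4, 5), n = 6)
  b <- spectrumData(c(5, 0, 1, 2, 2), n = 6)
  expect_equal(sfsCounts(foldSFS(a)) + sfsCounts(foldSFS(b)),
               sfsCounts(foldSFS(spectrumData(sfsCounts(a) + sfsCounts(b),
                                              n = 6))))
})

test_that("hypergeometric projection matches brute-force subsampling", {
  p <- projectSFS(spectrumData(c(0, 1, 0), n = 4), 2)
  expect_equal(sfsCounts(p), 2 / 3, tolerance = 1e-12)
  expect_equal(attr(p, "droppedMass"), 1 / 3, tolerance = 1e-12)
  ## m = n is the identity
  s <- spectrumData(c(2, 5, 1, 0, 3), n = 6)
  expect_identical(projectSFS(s, 6), s)
  ## brute-force Monte-Carlo oracle on a random spectrum
  set.seed(7)
  cnt <- c(4, 2, 0, 1, 3, 0, 2)
  proj <- sfsCounts(projectSFS(spectrumData(cnt, n = 8), 4))
  oracle <- bruteProject(cnt, n = 8, m = 4, reps = 40000)
  expect_equal(proj, oracle, tolerance = 0.03)
  ## projection preserves nonnegativity
  expect_true(all(proj >= 0))
  expect_error(projectSFS(spectrumData(c(1, 1, 1), n = 4), 5), "project up")
})

test_that("watterson sums cover constant and demographic densities", {
  expect_equal(wattersonSum(5), 1 + 1 / 2 + 1 / 3 + 1 / 4)
  expect_equal(wattersonSum(2), 1)
  expect_equal(wattersonSum(100), sum(1 / (1:99)), tolerance = 1e-12)
  expect_equal(wattersonSum(100), 5.177378, tolerance = 1e-6)
  dem <- demography(nu = c(1, 10), dur = c(Inf, 0.05))
  expect_equal(wattersonSum(10, dem), expectedSFS(dem, 10)@sumF)
})
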