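# Presets, X-model constraint propagation, per-epoch p recovery.

test_that("presets build the documented epoch structures", {
  g <- presetDemography("growth")
  expect_equal(nEpochs(g), 2L)
  expect_equal(epochs(g)$nu, c(1, 55))
  expect_equal(epochStartGen(g)[2], 205)
  expect_equal(ancestralSize(g), 7700)

  b <- presetDemography("bottleneck")
  expect_equal(nEpochs(b), 3L)
  expect_equal(epochSizes(b), c(14500, 1861, 100000))
  expect_equal(epochStartGen(b)[-1], c(2040, 920))

  cst <- presetDemography("constant")
  expect_equal(nEpochs(cst), 1L)
  expect_equal(epochs(cst)$nu, 1)

  bg <- presetDemography("bottlegrowth")
  expect_equal(epochs(bg)$change[3], "exponential")
  cx <- presetDemography("complex")
  expect_equal(nEpochs(cx), 4L)

  expect_error(presetDemography("nosuch"))
})

test_that("no-sex-bias constraints: nu_X = nu_A, tau_X = 4/3 tau_A, theta_X = 3/4 theta_A", {
  a2 <- demography(nu = c(1, 5), dur = c(Inf, 0.1), Nref = 1e4)
  d0 <- deriveXDemography(a2, 0.5)
  expect_equal(epochs(d0$dem)$nu[2], 5)
  expect_equal(epochs(d0$dem)$dur[2], 0.1 * 4 / 3)
  expect_equal(d0$NrefX, 7500)
  expect_equal(d0$thetaScale, 0.75)
})

test_that("constant and per-epoch sex-bias scale the X model as Q(p)", {
  a2 <- demography(nu = c(1, 5), dur = c(Inf, 0.1), Nref = 1e4)
  p0 <- 0.3
  d1 <- deriveXDemography(a2, p0)
  expect_equal(epochs(d1$dem)$nu[2], 5)  # constant p: same relative sizes
  expect_equal(epochSizes(d1$dem) / epochSizes(a2), rep(qRatio(p0), 2))
  ## two-epoch changing bias: nu_X = c2/c1 * nu_A
  d2 <- deriveXDemography(a2, c(0.3, 0.7))
  expect_equal(epochs(d2$dem)$nu[2], qRatio(0.7) / qRatio(0.3) * 5)
  expect_equal(epochs(d2$dem)$dur[2], 0.1 / qRatio(0.3))
})

test_that("derive + per-epoch recovery round-trips p exactly, any epoch structure", {
  auto <- demography(nu = c(1, 0.2, 7, 3), dur = c(Inf, 0.05, 0.02, 0.01),
                     change = c("instantaneous", "instantaneous",
                                "exponential", "instantaneous"),
                     Nref = 12000)
  set.seed(3)
  for (rep in 1:5) {
    pv <- runif(4, 0.05, 0.95)
    dx <- deriveXDemography(auto, pv)
    expect_equal(pPerEpochFromFit(epochSizes(auto), epochSizes(dx$dem)), pv,
                 tolerance = 1e-12)
    ## event times identical in generations
    expect_equal(epochStartGen(dx$dem)[-1], epochStartGen(auto)[-1],
                 tolerance = 1e-9)
  }
})

test_that("per-epoch p recovery matches the printed reference points", {
  expect_equal(pPerEpochFromFit(1, 0.75), 0.5)
  expect_equal(round(pPerEpochFromFit(1, 0.703), 2), 0.4)
  expect_equal(pPerEpochFromFit(1, 1), 0.875)
  expect_error(pPerEpochFromFit(0, 1), "must be > 0")
  expect_error(pPerEpochFromFit(c(1, 2), 1), "equal length")
})

test_that("census scaling by sex preserves the q ratio epoch-wise", {
  census <- presetDemography("bottleneck")
  p <- c(0.8, 0.2, 0.8)
  dA <- scaleDemographyBySex(census, p, "autosome")
  dX <- scaleDemographyBySex(census, p, "X")
  expect_equal(epochSizes(dX) / epochSizes(dA), qRatio(p))
  expect_equal(epochSizes(dA), reductionFactorA(p) * epochSizes(census))
  ## event times unchanged in generations
  expect_equal(epochStartGen(dA)[-1], epochStartGen(census)[-1])
  expect_equal(epochStartGen(dX)[-1], epochStartGen(census)[-1])
})

test_that("demography validity enforces the model invariants", {
  expect_error(demography(nu = c(2, 1), dur = c(Inf, 0.1)), "ancestral")
  expect_error(demography(nu = c(1, -1), dur = c(Inf, 0.1)), "nu must be")
  expect_error(demography(nu = c(1, 2), dur = c(Inf, -0.5)), "durations")
  expect_error(demography(nu = c(1, 2), dur = c(Inf, 205),
                          units = "generations"), "Nref")
})
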