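# Fitting procedure (autosomes first, then constrained X models), nested
# likelihood-ratio tests, and bootstrap machinery.

.modelParams <- function(model) {
  switch(model,
    constant = character(0),
    growth = c("nu", "T"),
    bottleneck = c("nuB", "nuF", "dB", "dF"),
    bottlegrowth = c("nuB", "nuF", "dB", "dF"),
    complex = c("nu1", "d1", "nuB", "dB", "nuF", "dF"),
    stop("unknown demographic model: ", model)
  )
}

.buildModel <- function(model, par) {
  switch(model,
    constant = demography(1, Inf),
    growth = demography(nu = c(1, par[["nu"]]), dur = c(Inf, par[["T"]])),
    bottleneck = demography(nu = c(1, par[["nuB"]], par[["nuF"]]),
                            dur = c(Inf, par[["dB"]], par[["dF"]])),
    bottlegrowth = demography(nu = c(1, par[["nuB"]], par[["nuF"]]),
                              dur = c(Inf, par[["dB"]], par[["dF"]]),
                              change = c("instantaneous", "instantaneous",
                                         "exponential")),
    complex = demography(nu = c(1, par[["nu1"]], par[["nuB"]], par[["nuF"]]),
                         dur = c(Inf, par[["d1"]], par[["dB"]], par[["dF"]]),
                         change = c("instantaneous", "instantaneous",
                                    "instantaneous", "exponential"))
  )
}

.defaultBounds <- function(parNames) {
  lower <- ifelse(grepl("^nu", parNames), 1e-3, 1e-5)
  upper <- ifelse(grepl("^nu", parNames), 1e3, 5)
  names(lower) <- names(upper) <- parNames
  list(lower = lower, upper = upper)
}

# Profile log-likelihood of a demographic shape: theta is profiled out
# analytically (theta-hat = S / (L * sumF)).
.profileLogLik <- function(s, dem) {
  dens <- expectedSFS(dem, sampleSize(s), folded = isFolded(s))
  sumF <- .sumFUnmasked(s, dens)
  if (sumF <= 0) return(list(ll = -Inf, theta = NA_real_))
  theta <- segSites(s) / (locusLength(s) * sumF)
  lam <- theta * locusLength(s) * dens@F
  list(ll = poissonLogLik(s, lam), theta = theta)
}

#' Fit a demographic model to an autosomal spectrum
#'
#' Maximizes the Poisson random field log-likelihood over the demographic
#' shape parameters, with the per-site theta profiled out analytically.
#' Initialization is a log-spaced grid search (optionally seeded with
#' \code{init}); optimization is Nelder-Mead simplex on log-parameters.
#' If the optimum lands on a parameter bound the optimizer is restarted
#' from a multiplicatively perturbed point (uniform in x[1/2, 2]), up to
#' \code{maxRestarts} times.
#'
#' @param s a \linkS4class{SpectrumData} (typically autosomal).
#' @param model demographic model name (see \code{\link{presetDemography}};
#'   durations here are free parameters in coalescent units).
#' @param mu per-site mutation rate used to anchor absolute sizes
#'   (default: the spectrum's \code{mu}).
#' @param lower,upper named bounds on the natural-scale parameters.
#' @param init optional named vector of starting values.
#' @param gridPoints grid-search points per parameter (0 = skip the grid
#'   and start from \code{init}).
#' @param maxGridEvals cap on the number of grid evaluations (a random
#'   subset is used above it).
#' @param maxRestarts retry budget on bound hits.
#' @return a \linkS4class{FitResult}.
#' @export
fitAutosomal <- function(s, model = c("constant", "growth", "bottleneck",
                                      "bottlegrowth", "complex"),
                         mu = mutationRate(s), lower = NULL, upper = NULL,
                         init = NULL, gridPoints = 3, maxGridEvals = 300,
                         maxRestarts = 5) {
  model <- match.arg(model)
  stopifnot(is(s, "SpectrumData"))
  if (segSites(s) <= 0) stop("empty spectrum: no segregating sites to fit")
  parNames <- .modelParams(model)
  if (model == "constant") {
    dem <- demography(1, Inf)
    pr <- .profileLogLik(s, dem)
    if (!is.na(mu) && !is.na(pr$theta)) dem@Nref <- pr$theta / (4 * mu)
    return(new("FitResult", model = dem, theta = pr$theta, loglik = pr$ll,
               converged = TRUE,
               trace = list(model = model, par = numeric(0), restarts = 0L,
                            boundHit = FALSE),
               pEstimates = numeric(0), level = "A"))
  }
  b <- .defaultBounds(parNames)
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  llo <- log(b$lower); lhi <- log(b$upper)
  k <- length(parNames)

  negLL <- function(lp) {
    if (any(lp < llo - 1e-9) || any(lp > lhi + 1e-9))
      return(1e12 + sum(pmax(lp - lhi, 0) + pmax(llo - lp, 0)))
    par <- stats::setNames(exp(lp), parNames)
    res <- tryCatch(.profileLogLik(s, .buildModel(model, par)),
                    error = function(e) list(ll = -Inf))
    if (!is.finite(res$ll)) 1e12 else -res$ll
  }

  ## grid-search initialization
  cand <- list()
  if (gridPoints > 0) {
    axes <- lapply(seq_len(k), function(i)
      seq(llo[i], lhi[i], length.out = gridPoints + 2L)[2:(gridPoints + 1L)])
    grid <- as.matrix(expand.grid(axes))
    if (nrow(grid) > maxGridEvals)
      grid <- grid[sample.int(nrow(grid), maxGridEvals), , drop = FALSE]
    cand <- lapply(seq_len(nrow(grid)), function(i) grid[i, ])
  }
  if (!is.null(init)) cand <- c(list(log(init[parNames])), cand)
  if (!length(cand))
    stop("no starting point: supply init or use gridPoints > 0")
  gridVals <- vapply(cand, negLL, numeric(1))

  runNM <- function(start) {
    o <- stats::optim(start, negLL, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    ## re-start the simplex once from the optimum: guards against
    ## premature simplex collapse
    stats::optim(o$par, negLL, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
  }

  ## optimize from the best few grid points and keep the best optimum
  nStarts <- min(3L, length(cand))
  starts <- cand[order(gridVals)[seq_len(nStarts)]]
  opts <- lapply(starts, runNM)
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]

  restarts <- 0L; boundHit <- FALSE
  repeat {
    atBound <- any(abs(opt$par - llo) < 1e-3) || any(abs(opt$par - lhi) < 1e-3)
    if (!atBound || restarts >= maxRestarts) {
      boundHit <- atBound
      break
    }
    restarts <- restarts + 1L
    start <- pmin(pmax(opt$par + log(stats::runif(k, 0.5, 2)), llo), lhi)
    cand2 <- runNM(start)
    if (cand2$value < opt$value) opt <- cand2
  }
  if (!is.finite(opt$value) || opt$value >= 1e12)
    stop("autosomal fit failed to converge; trace: ",
         paste(sprintf("%s=%.4g", parNames, exp(opt$par)), collapse = ", "))
  par <- stats::setNames(exp(opt$par), parNames)
  dem <- .buildModel(model, par)
  pr <- .profileLogLik(s, dem)
  if (!is.na(mu)) dem@Nref <- pr$theta / (4 * mu)
  new("FitResult", model = dem, theta = pr$theta, loglik = pr$ll,
      converged = (opt$convergence == 0L) && !boundHit,
      trace = list(model = model, par = par, restarts = restarts,
                   boundHit = boundHit, gridBest = min(gridVals),
                   optimCounts = opt$counts),
      pEstimates = numeric(0), level = "A")
}

.defaultTie <- function(T, freeAll = FALSE) {
  if (freeAll) return(seq_len(T))
  if (T == 3L) c(1L, 2L, 1L)          # tie p outside the bottleneck
  else if (T == 4L) c(1L, 1L, 2L, 1L) # complex: free the bottleneck epoch
  else seq_len(T)
}

# X log-likelihood at a per-epoch p vector given the autosomal fit
.xLogLik <- function(sX, autoFit, p, r) {
  dx <- deriveXDemography(autoFit@model, p, r = r)
  dens <- expectedSFS(dx$dem, sampleSize(sX), folded = isFolded(sX))
  thetaX <- dx$thetaScale * autoFit@theta
  lam <- thetaX * locusLength(sX) * dens@F
  list(ll = poissonLogLik(sX, lam), thetaX = thetaX, dem = dx$dem)
}

#' Fit the constrained X-chromosomal model given an autosomal fit
#'
#' The X demography is fully determined by the autosomal parameter
#' estimates and the per-epoch proportions of females (see
#' \code{\link{deriveXDemography}}); the X theta is fixed by the autosomal
#' theta, so the only free parameters are the sex ratios. Model levels:
#' \code{M0} (no sex-bias, all \eqn{p_t = 0.5}, zero free parameters),
#' \code{M1} (one shared \eqn{p}), \code{MT} (per-epoch \eqn{p_t} under the
#' tie structure; for a three-epoch bottleneck the default ties the epochs
#' outside the bottleneck).
#'
#' @param sX X-chromosomal \linkS4class{SpectrumData}.
#' @param autoFit a converged autosomal \linkS4class{FitResult}.
#' @param level \code{"M0"}, \code{"M1"} or \code{"MT"}.
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A}.
#' @param tie integer vector mapping epochs to free parameters (MT only).
#' @param freeAll free every epoch's p (MT only)?
#' @param pBounds search interval for each p.
#' @return a \linkS4class{FitResult}; its \code{loglik} is the joint
#'   autosomal + X log-likelihood and \code{pEstimates} the per-epoch p.
#' @export
fitXConstrained <- function(sX, autoFit, level = c("M0", "M1", "MT"), r = 1,
                            tie = NULL, freeAll = FALSE,
                            pBounds = c(0.01, 0.99)) {
  level <- match.arg(level)
  stopifnot(is(sX, "SpectrumData"), is(autoFit, "FitResult"))
  if (!isTRUE(autoFit@converged))
    warning("autosomal fit did not fully converge; X constraints inherit it")
  T <- nEpochs(autoFit@model)
  tie <- switch(level,
    M0 = rep(1L, T),
    M1 = rep(1L, T),
    MT = if (is.null(tie)) .defaultTie(T, freeAll) else as.integer(tie))
  nFree <- switch(level, M0 = 0L, M1 = 1L, MT = max(tie))

  evalP <- function(pFree) {
    p <- pFree[tie]
    .xLogLik(sX, autoFit, p, r)
  }

  if (level == "M0") {
    fit <- evalP(0.5)
    pHat <- rep(0.5, T)
  } else if (level == "M1" || nFree == 1L) {
    opt <- stats::optimize(function(pf) -evalP(pf)$ll,
                           interval = pBounds, tol = 1e-6)
    pHat <- rep(opt$minimum, T)
    fit <- evalP(opt$minimum)
  } else {
    ## seed every free parameter from the shared-p optimum
    m1 <- stats::optimize(function(pf) -.xLogLik(sX, autoFit,
                                                 rep(pf, T), r)$ll,
                          interval = pBounds, tol = 1e-4)
    start <- stats::qlogis(rep(m1$minimum, nFree))
    neg <- function(z) {
      pf <- stats::plogis(z)
      if (any(pf < pBounds[1]) || any(pf > pBounds[2])) return(1e12)
      -evalP(pf)$ll
    }
    opt <- stats::optim(start, neg, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-10))
    pFree <- stats::plogis(opt$par)
    pHat <- pFree[tie]
    fit <- evalP(pFree)
  }
  new("FitResult", model = fit$dem, theta = fit$thetaX,
      loglik = autoFit@loglik + fit$ll, converged = TRUE,
      trace = list(level = level, llX = fit$ll, llA = autoFit@loglik,
                   nFree = nFree, tie = tie, r = r),
      pEstimates = pHat, level = level)
}

.nFreeP <- function(fit) {
  if (fit@level == "A") stop("not an X-chromosomal model fit")
  fit@trace$nFree
}

#' Nested likelihood-ratio test between two X-chromosomal model fits
#'
#' \eqn{\Lambda = -2 (LL_{restricted} - LL_{general})} on the joint
#' autosomal + X log-likelihoods, with degrees of freedom equal to the
#' number of freed sex-ratio parameters. Small negative \eqn{\Lambda}
#' (optimizer tolerance, down to -1e-6) is clamped to zero with a warning;
#' anything lower is an optimizer-failure error.
#'
#' @param lo the restricted-model \linkS4class{FitResult}.
#' @param hi the general-model \linkS4class{FitResult} (must nest \code{lo}
#'   and share its autosomal fit).
#' @param critical source of the critical value: \code{"chisq"},
#'   \code{"empirical"} or \code{"parametric"} (the latter two require
#'   \code{critValue}).
#' @param alpha nominal level for the chi-square critical value.
#' @param critValue externally supplied critical value.
#' @return a \linkS4class{SexBiasTestResult}.
#' @export
lrtSexBias <- function(lo, hi, critical = c("chisq", "empirical", "parametric"),
                       alpha = 0.05, critValue = NULL) {
  critical <- match.arg(critical)
  stopifnot(is(lo, "FitResult"), is(hi, "FitResult"))
  ord <- c(M0 = 0L, M1 = 1L, MT = 2L)
  if (!(lo@level %in% names(ord)) || !(hi@level %in% names(ord)) ||
      ord[[lo@level]] >= ord[[hi@level]])
    stop("models are not nested: lo must be a restriction of hi")
  if (!isTRUE(all.equal(lo@trace$llA, hi@trace$llA)))
    stop("fits do not share the same autosomal model")
  df <- max(.nFreeP(hi) - .nFreeP(lo), 1L)
  lambda <- -2 * (lo@loglik - hi@loglik)
  if (lambda < -1e-6)
    stop(sprintf("negative LRT statistic (%.3g): optimizer failure", lambda))
  if (lambda < 0) {
    warning("slightly negative LRT statistic clamped to 0")
    lambda <- 0
  }
  cv <- if (critical == "chisq") stats::qchisq(1 - alpha, df) else {
    if (is.null(critValue))
      stop("critValue is required for empirical/parametric critical values")
    critValue
  }
  name <- if (lo@level == "M0") "Lambda0" else "Lambda1"
  ll <- c(lo@loglik, hi@loglik)
  names(ll) <- c(lo@level, hi@level)
  new("SexBiasTestResult",
      loglik = ll,
      lambda = stats::setNames(lambda, name),
      df = df,
      pvalue = stats::pchisq(lambda, df, lower.tail = FALSE),
      critical = cv, criticalSource = critical,
      reject = lambda > cv,
      pEstimates = list(lo = lo@pEstimates, hi = hi@pEstimates))
}

#' Closed-form constant-size likelihood-ratio test for sex-bias
#'
#' For a constant-size population the alternative is profiled analytically:
#' the sex ratio from the segregating-site ratio and theta from the joint
#' MLE at that sex ratio; the null uses the joint MLE with the X theta tied
#' to 3/4 of the autosomal one. \eqn{\Lambda_0 = -2(LL_0 - LL_1)} is
#' approximately chi-square with 1 df under the null. When the closed-form
#' estimate falls outside (0, 1) the alternative is maximized numerically
#' over the valid domain (the raw estimate is still reported).
#'
#' @param sA,sX autosomal and X \linkS4class{SpectrumData}.
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A}.
#' @param critical,alpha,critValue as in \code{\link{lrtSexBias}}.
#' @param densA,densX optional densities (default constant size).
#' @return a \linkS4class{SexBiasTestResult}; \code{pEstimates} carries the
#'   raw \eqn{\tilde p}, the value used for the likelihood, and both theta
#'   MLEs.
#' @export
lrtConstantSize <- function(sA, sX, r = 1,
                            critical = c("chisq", "empirical", "parametric"),
                            alpha = 0.05, critValue = NULL,
                            densA = NULL, densX = NULL) {
  critical <- match.arg(critical)
  densA <- .densityFor(sA, densA); densX <- .densityFor(sX, densX)
  lamParts <- function(thetaSite, fA, fX) {
    list(A = thetaSite * fA * locusLength(sA) * densA@F,
         X = thetaSite * fX * r * locusLength(sX) * densX@F)
  }
  ll <- function(lam) poissonLogLik(sA, lam$A) + poissonLogLik(sX, lam$X)

  th0 <- thetaNullJoint(sA, sX, r = r, densA = densA, densX = densX)
  LL0 <- ll(lamParts(th0, 1, 0.75))

  pRaw <- pTildeConstant(sA, sX, r = r, densA = densA, densX = densX)
  eps <- 1e-3
  if (pRaw > eps && pRaw < 1 - eps) {
    pUse <- pRaw
  } else {
    opt <- stats::optimize(function(p) {
      th <- thetaAltJoint(sA, sX, p, r = r, densA = densA, densX = densX)
      -ll(lamParts(th, reductionFactorA(p), reductionFactorX(p)))
    }, interval = c(eps, 1 - eps), tol = 1e-7)
    pUse <- opt$minimum
  }
  th1 <- thetaAltJoint(sA, sX, pUse, r = r, densA = densA, densX = densX)
  LL1 <- ll(lamParts(th1, reductionFactorA(pUse), reductionFactorX(pUse)))

  lambda <- -2 * (LL0 - LL1)
  if (lambda < -1e-6)
    stop(sprintf("negative LRT statistic (%.3g)", lambda))
  lambda <- max(lambda, 0)
  cv <- if (critical == "chisq") stats::qchisq(1 - alpha, 1) else {
    if (is.null(critValue))
      stop("critValue is required for empirical/parametric critical values")
    critValue
  }
  new("SexBiasTestResult",
      loglik = c(LL0 = LL0, LL1 = LL1),
      lambda = c(Lambda0 = lambda), df = 1,
      pvalue = stats::pchisq(lambda, 1, lower.tail = FALSE),
      critical = cv, criticalSource = critical, reject = lambda > cv,
      pEstimates = list(pTilde = pRaw, pUsed = pUse,
                        thetaNull = th0, thetaAlt = th1))
}

#' Parametric bootstrap for confidence intervals and critical values
#'
#' Re-simulates the joint dataset under a fitted X model (independent-sites
#' Poisson sampling from the fitted expected spectra, or linked coalescent
#' loci), refits the autosomal and X model ladder on each replicate, and
#' records parameters and LRT statistics. Confidence intervals are the
#' central 95% of replicate values; \eqn{\Lambda} critical values the 95th
#' percentiles.
#'
#' @param autoFit autosomal \linkS4class{FitResult}.
#' @param xFit X-chromosomal \linkS4class{FitResult} (the model simulated
#'   under; typically the null of the test being calibrated).
#' @param sA,sX the observed spectra (templates for size/length).
#' @param nReps bootstrap replicates (> 0).
#' @param r mutation-rate ratio.
#' @param tie,freeAll forwarded to the MT refits.
#' @param linked simulate linked loci (requires \code{nLoci} and
#'   \code{locusL})?
#' @param nLoci,locusL linked-mode locus structure of the original data.
#' @param failFrac error out if more than this fraction of replicates fail.
#' @param seed optional RNG seed.
#' @param ci confidence level for the intervals.
#' @return list with \code{replicates} (data.frame), \code{ci} (per
#'   quantity), and \code{critical} (\code{Lambda0}, \code{Lambda1} 95th
#'   percentiles).
#' @export
parametricBootstrap <- function(autoFit, xFit, sA, sX, nReps = 100, r = 1,
                                tie = NULL, freeAll = FALSE, linked = FALSE,
                                nLoci = NULL, locusL = NULL, failFrac = 0.1,
                                seed = NULL, ci = 0.95) {
  if (is.null(nReps) || nReps < 1) stop("nReps must be >= 1")
  stopifnot(is(autoFit, "FitResult"), is(xFit, "FitResult"))
  if (!is.null(seed)) set.seed(seed)
  densA <- expectedSFS(autoFit@model, sampleSize(sA), folded = isFolded(sA))
  densX <- expectedSFS(xFit@model, sampleSize(sX), folded = isFolded(sX))
  lamA <- autoFit@theta * locusLength(sA) * densA@F
  lamX <- xFit@theta * locusLength(sX) * densX@F
  if (linked && (is.null(nLoci) || is.null(locusL)))
    stop("linked mode requires nLoci and locusL")
  model <- autoFit@trace$model
  muA <- mutationRate(sA)

  one <- function() {
    if (linked) {
      cA <- colSums(simulateCoalescentSFS(autoFit@model, sampleSize(sA),
                                          muA, locusL, nLoci))
      cX <- colSums(simulateCoalescentSFS(xFit@model, sampleSize(sX),
                                          mutationRate(sX), locusL, nLoci))
      if (isFolded(sA)) cA <- .foldVector(cA, sampleSize(sA))
      if (isFolded(sX)) cX <- .foldVector(cX, sampleSize(sX))
    } else {
      cA <- stats::rpois(length(lamA), lamA)
      cX <- stats::rpois(length(lamX), lamX)
    }
    rA <- spectrumData(cA, sampleSize(sA), folded = isFolded(sA),
                       L = locusLength(sA), mu = muA)
    rX <- spectrumData(cX, sampleSize(sX), folded = isFolded(sX),
                       L = locusLength(sX), mu = mutationRate(sX),
                       chromClass = "X")
    ## replicate refits are warm-started from the observed-data optimum;
    ## flat-ridge bound hits there are tracked, not re-warned per replicate
    suppressWarnings({
      fa <- fitAutosomal(rA, model = model, mu = muA,
                         init = autoFit@trace$par, gridPoints = 0,
                         maxRestarts = 1)
      f0 <- fitXConstrained(rX, fa, "M0", r = r)
      f1 <- fitXConstrained(rX, fa, "M1", r = r)
      fT <- fitXConstrained(rX, fa, "MT", r = r, tie = tie, freeAll = freeAll)
    })
    c(theta = fa@theta,
      stats::setNames(fa@trace$par, paste0("auto.", names(fa@trace$par))),
      p1 = f1@pEstimates[1],
      stats::setNames(fT@pEstimates, paste0("pT", seq_along(fT@pEstimates))),
      Lambda0 = -2 * (f0@loglik - f1@loglik),
      Lambda1 = -2 * (f1@loglik - fT@loglik))
  }

  reps <- vector("list", nReps)
  nfail <- 0L
  for (b in seq_len(nReps)) {
    reps[[b]] <- tryCatch(one(), error = function(e) NULL)
    if (is.null(reps[[b]])) nfail <- nfail + 1L
  }
  if (nfail > failFrac * nReps)
    stop(sprintf("%d of %d bootstrap replicates failed", nfail, nReps))
  tab <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  a <- (1 - ci) / 2
  cis <- apply(tab, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  crit <- c(Lambda0 = unname(stats::quantile(pmax(tab[, "Lambda0"], 0), 0.95)),
            Lambda1 = unname(stats::quantile(pmax(tab[, "Lambda1"], 0), 0.95)))
  list(replicates = as.data.frame(tab), ci = cis, critical = crit,
       nFailed = nfail)
}

#' Block bootstrap over genomic loci
#'
#' Resamples 1 Mb blocks of loci with replacement (blocks kept intact, no
#' within-block resampling), rebuilds the aggregate spectra, applies a
#' statistic, and reports the standard deviation and percentile interval
#' across iterations.
#'
#' @param lociA,lociX per-locus unfolded SFS count matrices (rows = loci).
#' @param coordsA,coordsX data.frames with \code{chrom} and \code{pos} per
#'   locus row.
#' @param statistic \code{function(countsA, countsX)} returning a numeric
#'   vector, applied to the aggregate class counts.
#' @param blockSize block width in bp (default 1 Mb).
#' @param iters bootstrap iterations (default 100).
#' @param seed optional RNG seed.
#' @param ci confidence level.
#' @return list with \code{estimate}, \code{se}, \code{ci},
#'   \code{replicates}.
#' @export
blockBootstrap <- function(lociA, lociX, coordsA, coordsX, statistic,
                           blockSize = 1e6, iters = 100, seed = NULL,
                           ci = 0.95) {
  lociA <- as.matrix(lociA); lociX <- as.matrix(lociX)
  stopifnot(nrow(lociA) == nrow(coordsA), nrow(lociX) == nrow(coordsX))
  if (!is.null(seed)) set.seed(seed)
  blkA <- paste(coordsA$chrom, floor(coordsA$pos / blockSize))
  blkX <- paste(coordsX$chrom, floor(coordsX$pos / blockSize))
  uA <- unique(blkA); uX <- unique(blkX)
  if (length(uA) < 2L || length(uX) < 2L)
    stop("at least 2 blocks per class are required")
  est <- statistic(colSums(lociA), colSums(lociX))
  reps <- vapply(seq_len(iters), function(b) {
    rA <- unlist(lapply(sample(uA, replace = TRUE), function(g) which(blkA == g)))
    rX <- unlist(lapply(sample(uX, replace = TRUE), function(g) which(blkX == g)))
    statistic(colSums(lociA[rA, , drop = FALSE]),
              colSums(lociX[rX, , drop = FALSE]))
  }, numeric(length(est)))
  reps <- matrix(reps, ncol = iters)
  a <- (1 - ci) / 2
  list(estimate = est,
       se = apply(reps, 1, stats::sd),
       ci = apply(reps, 1, stats::quantile, probs = c(a, 1 - a)),
       replicates = t(reps))
}
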