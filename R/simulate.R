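# Synthetic-data generation: independent-sites Poisson SFS sampling, a
# linked-loci coalescent sampler with the sex-bias scalings of theta and
# rho, and experiment runners for power/bias grids.

#' Draw a Poisson SFS from per-class expected counts
#'
#' Independent Poisson draws per frequency class (the Poisson random field
#' sampling model).
#'
#' @param means numeric vector of non-negative per-class means.
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of counts.
#' @export
sampleSFSPoisson <- function(means, seed = NULL) {
  if (any(means < 0) || any(!is.finite(means)))
    stop("means must be finite and non-negative")
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(length(means), means)
}

#' Sex-bias scalings of the population mutation and recombination rates
#'
#' \eqn{\theta_A = f_A(p)\theta}, \eqn{\theta_X = f_X(p)\theta},
#' \eqn{\rho_A = f_A(p)\rho}, and — because the X recombines only in
#' females — \eqn{\rho_X = f_X(p) \cdot 2p/(1+p) \cdot \rho}.
#'
#' @param p proportion of breeding females in (0, 1).
#' @param theta per-site population-scaled mutation rate of the census-size
#'   population.
#' @param rho per-site population-scaled recombination rate.
#' @return list with \code{thetaA}, \code{thetaX}, \code{rhoA}, \code{rhoX}.
#' @examples
#' scaledRates(0.5, 0.001, 0.001)  # thetaX/thetaA = 0.75, rhoX/rhoA = 0.5
#' @export
scaledRates <- function(p, theta, rho) {
  fA <- reductionFactorA(p); fX <- reductionFactorX(p)
  list(thetaA = fA * theta, thetaX = fX * theta,
       rhoA = fA * rho, rhoX = fX * (2 * p) / (1 + p) * rho)
}

#' Simulation configuration
#'
#' Bundles the census demography, per-epoch sex ratios and sampling design
#' of a simulated X + autosome dataset.
#'
#' @param demography census \linkS4class{Demography} (absolute
#'   \code{Nref} required).
#' @param p per-epoch proportion of females (recycled to the number of
#'   epochs).
#' @param nA,nX sampled chromosomes per class.
#' @param L locus length in bp.
#' @param nLoci number of independent loci per class.
#' @param mu autosomal per-site per-generation mutation rate.
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A} (1 for the simulation
#'   designs whose scalings act on sizes, not rates).
#' @param linked simulate linked sites (one coalescent tree per locus)
#'   instead of independent-sites Poisson sampling?
#' @param folded return folded spectra?
#' @param seed optional RNG seed.
#' @return a list of class \code{"simConfig"}.
#' @export
simConfig <- function(demography, p = 0.5, nA = 100, nX = 100, L = 1e5,
                      nLoci = 100, mu = 1.5e-8, r = 1, linked = FALSE,
                      folded = FALSE, seed = NULL) {
  stopifnot(is(demography, "Demography"))
  if (is.na(demography@Nref))
    stop("simulation requires a census demography with absolute Nref")
  .checkP(p)
  stopifnot(nA >= 2, nX >= 2, L > 0, nLoci >= 1, mu > 0, r > 0)
  structure(list(demography = demography, p = p, nA = as.integer(nA),
                 nX = as.integer(nX), L = L, nLoci = as.integer(nLoci),
                 mu = mu, r = r, linked = isTRUE(linked),
                 folded = isTRUE(folded), seed = seed),
            class = "simConfig")
}

# One coalescent tree under piecewise-constant sizes; returns branch length
# subtending b leaves, b = 1..n-1, in units of 2*Nref generations.
.simTreeLengths <- function(pieces, n) {
  bnd <- c(cumsum(pieces$s), Inf)
  nus <- c(pieces$nu, 1)
  desc <- rep(1L, n)
  birth <- numeric(n)
  lenB <- numeric(n - 1L)
  k <- n
  t <- 0
  piece <- findInterval(0, bnd, left.open = TRUE) + 1L
  while (k > 1L) {
    w <- stats::rexp(1L, rate = k * (k - 1L) / 2)  # standard coalescent units
    repeat {
      avail <- (bnd[piece] - t) / nus[piece]
      if (w <= avail) { t <- t + w * nus[piece]; break }
      w <- w - avail
      t <- bnd[piece]
      piece <- piece + 1L
    }
    ab <- sample.int(k, 2L)
    a <- ab[1L]; b <- ab[2L]
    lenB[desc[a]] <- lenB[desc[a]] + (t - birth[a])
    lenB[desc[b]] <- lenB[desc[b]] + (t - birth[b])
    desc[a] <- desc[a] + desc[b]
    birth[a] <- t
    desc[b] <- desc[k]; birth[b] <- birth[k]
    k <- k - 1L
  }
  lenB
}

#' Coalescent simulation of per-locus SFS
#'
#' Simulates independent loci under the Kingman coalescent with
#' piecewise-constant (or internally discretized exponential) population
#' sizes, dropping Poisson mutations on branches. Sites within a locus are
#' completely linked (one tree per locus), so this is the "linked" sampling
#' mode; the mean SFS equals the independent-sites expectation while the
#' variance reflects linkage.
#'
#' @param dem a \linkS4class{Demography} with absolute \code{Nref}.
#' @param n sampled chromosomes.
#' @param mu per-site per-generation mutation rate.
#' @param L locus length in bp.
#' @param nLoci number of independent loci.
#' @param seed optional RNG seed.
#' @return matrix of counts, rows = loci, columns = classes \eqn{1..n-1}.
#' @export
simulateCoalescentSFS <- function(dem, n, mu, L, nLoci, seed = NULL) {
  stopifnot(is(dem, "Demography"), n >= 2)
  if (is.na(dem@Nref)) stop("an absolute Nref is required")
  if (!is.null(seed)) set.seed(seed)
  pieces <- .backwardPieces(dem)
  thetaL2 <- 4 * dem@Nref * mu * L / 2
  out <- matrix(0, nrow = nLoci, ncol = n - 1L)
  for (l in seq_len(nLoci)) {
    lenB <- .simTreeLengths(pieces, n)
    out[l, ] <- stats::rpois(n - 1L, thetaL2 * lenB)
  }
  out
}

#' Simulate a paired autosomal and X-chromosomal dataset
#'
#' The census trajectory is scaled into the two locus classes
#' (\eqn{N_{tA} = f_A(p_t) N_t}, \eqn{N_{tX} = f_X(p_t) N_t}). In unlinked
#' mode the per-locus SFS are independent Poisson draws from the exact
#' expected spectra; in linked mode each locus is a coalescent tree.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with aggregate \code{sfsA}, \code{sfsX}
#'   (\linkS4class{SpectrumData}, \code{L} = total callable length), the
#'   per-locus count matrices \code{lociA}, \code{lociX}, the class
#'   demographies, and the expected per-locus means.
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  demA <- scaleDemographyBySex(cfg$demography, cfg$p, "autosome")
  demX <- scaleDemographyBySex(cfg$demography, cfg$p, "X")
  muX <- cfg$r * cfg$mu
  thA <- 4 * demA@Nref * cfg$mu    # per site
  thX <- 4 * demX@Nref * muX
  FA <- expectedSFS(demA, cfg$nA); FX <- expectedSFS(demX, cfg$nX)
  lamA <- thA * cfg$L * FA@F
  lamX <- thX * cfg$L * FX@F
  if (cfg$linked) {
    lociA <- simulateCoalescentSFS(demA, cfg$nA, cfg$mu, cfg$L, cfg$nLoci)
    lociX <- simulateCoalescentSFS(demX, cfg$nX, muX, cfg$L, cfg$nLoci)
  } else {
    lociA <- matrix(stats::rpois(cfg$nLoci * (cfg$nA - 1L), rep(lamA, each = cfg$nLoci)),
                    nrow = cfg$nLoci)
    lociX <- matrix(stats::rpois(cfg$nLoci * (cfg$nX - 1L), rep(lamX, each = cfg$nLoci)),
                    nrow = cfg$nLoci)
  }
  Ltot <- cfg$L * cfg$nLoci
  sfsA <- spectrumData(colSums(lociA), n = cfg$nA, L = Ltot, mu = cfg$mu,
                       chromClass = "autosome")
  sfsX <- spectrumData(colSums(lociX), n = cfg$nX, L = Ltot, mu = muX,
                       chromClass = "X")
  if (cfg$folded) { sfsA <- foldSFS(sfsA); sfsX <- foldSFS(sfsX) }
  list(sfsA = sfsA, sfsX = sfsX, lociA = lociA, lociX = lociX,
       demA = demA, demX = demX, meansA = lamA, meansX = lamX,
       thetaA = thA, thetaX = thX)
}

#' Preset simulation experiments
#'
#' The study designs used throughout the package:
#' \describe{
#'   \item{constant}{constant size, 1000 unlinked 5 kb regions, 40 autosomal
#'     and 30 X chromosomes (10 males + 10 females), per-site theta set so
#'     the expected total number of segregating sites is 427.}
#'   \item{expansion}{55-fold instantaneous growth 205 generations ago,
#'     ancestral size 7,700; 500 chromosomes; 1000 x 5 kb;
#'     mu = 1.5e-8.}
#'   \item{expansion_methods}{ten-fold growth 100 generations ago, ancestral
#'     size 10,000; 40 chromosomes; mu = 1.5e-8.}
#'   \item{bottleneck}{three-epoch bottleneck (14,500 to 1,861 between 2,040
#'     and 920 generations ago, then 100,000); 100 chromosomes; 100 x 100 kb
#'     loci; mu = 1.5e-8.}
#' }
#'
#' @param experiment preset name.
#' @param p per-epoch proportion of females.
#' @param ... overrides passed to \code{\link{simConfig}}.
#' @return a \code{\link{simConfig}}.
#' @export
experimentConfig <- function(experiment = c("constant", "expansion",
                                            "expansion_methods", "bottleneck"),
                             p = 0.5, ...) {
  experiment <- match.arg(experiment)
  base <- switch(experiment,
    constant = {
      ## theta chosen so E[S_A + S_X] = 427 at p = 0.5 over 1000 x 5 kb
      nA <- 40L; nX <- 30L; L <- 5000; nLoci <- 1000L
      HA <- expectedSFSConstant(nA)@sumF; HX <- expectedSFSConstant(nX)@sumF
      theta <- 427 / (L * nLoci * (HA + 0.75 * HX))
      Nanc <- theta / (4 * 1.5e-8)
      list(demography = presetDemography("constant", list(Nanc = Nanc)),
           nA = nA, nX = nX, L = L, nLoci = nLoci, mu = 1.5e-8)
    },
    expansion = list(demography = presetDemography("growth"),
                     nA = 500L, nX = 500L, L = 5000, nLoci = 1000L,
                     mu = 1.5e-8),
    expansion_methods = list(demography = presetDemography("growth_methods"),
                             nA = 40L, nX = 40L, L = 5000, nLoci = 1000L,
                             mu = 1.5e-8),
    bottleneck = list(demography = presetDemography("bottleneck"),
                      nA = 100L, nX = 100L, L = 1e5, nLoci = 100L,
                      mu = 1.5e-8)
  )
  args <- utils::modifyList(c(base, list(p = p)), list(...))
  do.call(simConfig, args)
}

#' Power / bias grid experiments
#'
#' For each grid cell: simulate, estimate, test, and record rejections and
#' estimator values. \code{"constant"} uses the closed-form constant-size
#' LRT; the fit-based experiments run the full autosomal-then-X pipeline.
#'
#' @param experiment one of \code{"constant"}, \code{"expansion"},
#'   \code{"bottleneck_constant"}, \code{"bottleneck_changing"}.
#' @param pGrid for constant-bias experiments a vector of p values; for
#'   \code{"bottleneck_changing"} a 2-column matrix/data.frame of
#'   (p outside, p during) pairs (p after = p outside).
#' @param reps replicates per cell.
#' @param seed RNG seed.
#' @param critValue critical value for rejection (default: chi-square at
#'   \code{alpha}).
#' @param alpha nominal level.
#' @param ... overrides forwarded to \code{\link{experimentConfig}}.
#' @return data.frame with one row per (cell, replicate): test statistics,
#'   rejection flags and estimator values.
#' @export
runPowerGrid <- function(experiment = c("constant", "expansion",
                                        "bottleneck_constant",
                                        "bottleneck_changing"),
                         pGrid, reps = 10, seed = NULL, critValue = NULL,
                         alpha = 0.05, ...) {
  experiment <- match.arg(experiment)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  cells <- if (experiment == "bottleneck_changing") {
    m <- as.matrix(pGrid); stopifnot(ncol(m) == 2); m
  } else cbind(as.numeric(pGrid), as.numeric(pGrid))
  out <- vector("list", nrow(cells) * reps)
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    p1 <- cells[ci, 1]; p2 <- cells[ci, 2]
    for (rep in seq_len(reps)) {
      row <- row + 1L
      out[[row]] <- .powerGridCell(experiment, p1, p2, critValue, alpha, ...)
      out[[row]]$p1 <- p1; out[[row]]$p2 <- p2; out[[row]]$rep <- rep
    }
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df$experiment <- experiment
  df
}

.powerGridCell <- function(experiment, p1, p2, critValue, alpha, ...) {
  if (experiment == "constant") {
    cfg <- experimentConfig("constant", p = p1, ...)
    d <- simulateDataset(cfg)
    tst <- lrtConstantSize(d$sfsA, d$sfsX,
                           critical = if (is.null(critValue)) "chisq" else "empirical",
                           alpha = alpha, critValue = critValue)
    pp <- pPiEstimator(piFromSFS(d$sfsA), piFromSFS(d$sfsX))
    return(list(lambda0 = tst@lambda[["Lambda0"]], reject0 = tst@reject[[1]],
                lambda1 = NA_real_, reject1 = NA,
                pTilde = tst@pEstimates$pTilde, pPi = pp$pPi,
                failed = FALSE))
  }
  preset <- if (experiment == "expansion") "expansion" else "bottleneck"
  model <- if (experiment == "expansion") "growth" else "bottleneck"
  pvec <- if (preset == "bottleneck") c(p1, p2, p1) else p1
  cfg <- experimentConfig(preset, p = pvec, ...)
  d <- simulateDataset(cfg)
  res <- tryCatch({
    fa <- fitAutosomal(d$sfsA, model = model, mu = cfg$mu)
    f0 <- fitXConstrained(d$sfsX, fa, level = "M0", r = cfg$r)
    f1 <- fitXConstrained(d$sfsX, fa, level = "M1", r = cfg$r)
    fT <- fitXConstrained(d$sfsX, fa, level = "MT", r = cfg$r)
    cv <- critValue
    t0 <- lrtSexBias(f0, f1, critical = if (is.null(cv)) "chisq" else "parametric",
                     alpha = alpha, critValue = cv)
    t1 <- lrtSexBias(f1, fT, critical = if (is.null(cv)) "chisq" else "parametric",
                     alpha = alpha, critValue = cv)
    pp <- pPiEstimator(piFromSFS(d$sfsA), piFromSFS(d$sfsX))
    list(lambda0 = t0@lambda[[1]], reject0 = t0@reject[[1]],
         lambda1 = t1@lambda[[1]], reject1 = t1@reject[[1]],
         pTilde = f1@pEstimates[1], pPi = pp$pPi, failed = FALSE)
  }, error = function(e) {
    list(lambda0 = NA_real_, reject0 = NA, lambda1 = NA_real_, reject1 = NA,
         pTilde = NA_real_, pPi = NA_real_, failed = TRUE)
  })
  res
}
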