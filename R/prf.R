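# Poisson random field log-likelihoods and theta estimators.

# Resolve a density for a spectrum: default is the constant-size density at
# the spectrum's sample size, folded to match.
.densityFor <- function(s, dens = NULL) {
  if (is.null(dens)) {
    dens <- expectedSFSConstant(sampleSize(s))
    if (isFolded(s)) dens <- foldSFS(dens)
  }
  if (dens@n != sampleSize(s) || dens@folded != isFolded(s))
    stop("density does not match the spectrum (n or folded flag)")
  dens
}

# Sum of F over unmasked classes (masked entries are excluded from both the
# site totals and the denominators, consistently).
.sumFUnmasked <- function(s, dens) sum(dens@F[!sfsMask(s)])

#' Poisson random field log-likelihood
#'
#' The log-likelihood of an observed SFS given per-class expected counts
#' \eqn{\lambda_i}: \eqn{\sum_i (-\lambda_i + s_i \log \lambda_i -
#' \log s_i!)} over unmasked classes. The \eqn{\log s_i!} term is retained
#' (via \code{lgamma}) so reported log-likelihoods are absolute. The joint
#' autosome + X log-likelihood is the sum of the two class log-likelihoods.
#'
#' @param observed a \linkS4class{SpectrumData} or a numeric count vector.
#' @param expected numeric vector of per-class expected counts.
#' @return the log-likelihood (numeric scalar).
#' @examples
#' poissonLogLik(c(1, 0), c(1, 0.5))  # -1.5
#' @export
poissonLogLik <- function(observed, expected) {
  if (is(observed, "SpectrumData")) {
    keep <- !sfsMask(observed)
    s <- sfsCounts(observed)[keep]
    lam <- expected[keep]
  } else {
    s <- observed
    lam <- expected
  }
  if (length(s) != length(lam))
    stop("observed and expected must have the same length")
  bad <- lam <= 0 & s > 0
  if (any(bad))
    stop("non-positive expected count on a class with observed sites")
  zz <- lam == 0  # s == 0 there: contributes 0
  s <- s[!zz]; lam <- lam[!zz]
  ## explicit Poisson log-density via log-gamma: identical to dpois() for
  ## integer counts, and well-defined for averaged (non-integer) spectra
  sum(-lam + s * log(lam) - lgamma(s + 1))
}

#' Maximum likelihood estimate of theta from one spectrum
#'
#' \eqn{\hat\theta = S / \sum_i F(i)} (per locus): with the constant-size
#' density this is the Watterson estimator.
#'
#' @param s a \linkS4class{SpectrumData}.
#' @param dens optional \linkS4class{SFSDensity} (default: constant size at
#'   the spectrum's sample size).
#' @param perSite divide by the callable length \code{L}?
#' @return numeric theta estimate.
#' @examples
#' thetaMLE(spectrumData(c(5, 3, 1, 1), n = 5))  # 10 / (1+1/2+1/3+1/4)
#' @export
thetaMLE <- function(s, dens = NULL, perSite = FALSE) {
  dens <- .densityFor(s, dens)
  sumF <- .sumFUnmasked(s, dens)
  if (sumF <= 0) stop("sum of SFS density is zero; theta is undefined")
  th <- segSites(s) / sumF
  if (perSite) th / locusLength(s) else th
}

#' Joint null-model theta MLE (no sex-bias)
#'
#' Under \eqn{p = 0.5} the X-chromosomal theta is 3/4 of the autosomal one
#' (times the mutation-rate ratio r), and the joint MLE of the per-site
#' theta from both spectra is
#' \deqn{\tilde\theta_0 = (S_A + S_X) /
#'   (L_A \sum F_A + r \cdot 3/4 \cdot L_X \sum F_X).}
#'
#' @param sA,sX autosomal and X-chromosomal \linkS4class{SpectrumData}.
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A} (1 reproduces the
#'   equal-rate form).
#' @param densA,densX optional densities (default: constant size).
#' @return per-site theta estimate (numeric).
#' @export
thetaNullJoint <- function(sA, sX, r = 1, densA = NULL, densX = NULL) {
  if (missing(sA) || missing(sX) || is.null(sA) || is.null(sX))
    stop("both autosomal and X-chromosomal spectra are required")
  densA <- .densityFor(sA, densA); densX <- .densityFor(sX, densX)
  den <- locusLength(sA) * .sumFUnmasked(sA, densA) +
    r * 0.75 * locusLength(sX) * .sumFUnmasked(sX, densX)
  if (den <= 0) stop("zero denominator in joint theta MLE")
  (segSites(sA) + segSites(sX)) / den
}

#' Joint alternative-model theta MLE at a given sex ratio
#'
#' With reduction factors \eqn{\theta_A = f_A(p)\theta} and
#' \eqn{\theta_X = f_X(p) r \theta}:
#' \deqn{\tilde\theta = (S_A + S_X) /
#'   (f_A(p) L_A \sum F_A + r f_X(p) L_X \sum F_X).}
#' At \code{p = 0.5} this equals \code{\link{thetaNullJoint}}.
#'
#' @inheritParams thetaNullJoint
#' @param p proportion of breeding females in (0, 1).
#' @return per-site theta estimate (numeric).
#' @export
thetaAltJoint <- function(sA, sX, p, r = 1, densA = NULL, densX = NULL) {
  if (missing(sA) || missing(sX) || is.null(sA) || is.null(sX))
    stop("both autosomal and X-chromosomal spectra are required")
  densA <- .densityFor(sA, densA); densX <- .densityFor(sX, densX)
  den <- reductionFactorA(p) * locusLength(sA) * .sumFUnmasked(sA, densA) +
    r * reductionFactorX(p) * locusLength(sX) * .sumFUnmasked(sX, densX)
  if (den <= 0) stop("zero denominator in joint theta MLE")
  (segSites(sA) + segSites(sX)) / den
}
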