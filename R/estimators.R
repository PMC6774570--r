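# Closed-form and diversity-based sex-bias estimators.

#' Closed-form constant-size estimator of the proportion of females
#'
#' From the ratio of autosomal to X-chromosomal segregating sites under a
#' constant-size model:
#' \deqn{\tilde p = 2 - \frac{9\, S_A\, L_X \sum_j F_X(j)}
#'                           {8\, r\, S_X\, L_A \sum_i F_A(i)}.}
#' With \code{r = 1} this is the equal-mutation-rate form. Values outside
#' (0, 1) are returned as-is with an \code{"outOfRange"} attribute.
#'
#' @param sA,sX autosomal and X-chromosomal \linkS4class{SpectrumData};
#'   their \code{L} slots supply the callable lengths.
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A}.
#' @param densA,densX optional \linkS4class{SFSDensity} objects (default:
#'   constant size at each spectrum's sample size).
#' @return the estimate \eqn{\tilde p} (numeric).
#' @export
pTildeConstant <- function(sA, sX, r = 1, densA = NULL, densX = NULL) {
  densA <- .densityFor(sA, densA); densX <- .densityFor(sX, densX)
  SX <- segSites(sX)
  if (SX <= 0) stop("no X-chromosomal segregating sites; p is undefined")
  SA <- segSites(sA)
  Qhat <- (SX * locusLength(sA) * .sumFUnmasked(sA, densA)) /
    (r * SA * locusLength(sX) * .sumFUnmasked(sX, densX))
  as.numeric(pFromQ(Qhat))
}

#' Per-site pairwise nucleotide diversity from an SFS
#'
#' \eqn{\pi = \sum_i \frac{2 i (n-i)}{n(n-1)} s_i / L}. For folded spectra
#' the same weight applies to each minor-allele class (classes \eqn{i} and
#' \eqn{n-i} share it). Masked classes are excluded.
#'
#' @param s a \linkS4class{SpectrumData}.
#' @return per-site diversity (numeric).
#' @examples
#' piFromSFS(spectrumData(5, n = 2, L = 100))  # 0.05
#' @export
piFromSFS <- function(s) {
  n <- sampleSize(s)
  i <- seq_along(sfsCounts(s))
  w <- 2 * i * (n - i) / (n * (n - 1))
  keep <- !sfsMask(s)
  sum(w[keep] * sfsCounts(s)[keep]) / locusLength(s)
}

#' Diversity-ratio estimator of the proportion of females
#'
#' \eqn{Q_\pi = (\pi_X / \pi_A) / r} and
#' \eqn{p_\pi = 2 - 9/(8 Q_\pi)}. This estimator does not model population
#' size change and is biased by recent growth or bottlenecks; out-of-range
#' values are informative and returned flagged rather than rejected.
#'
#' @param piA,piX per-site diversities (autosomes, X).
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A} (1 for simulations whose
#'   size scalings already absorb the rates).
#' @return list with \code{Qpi}, \code{pPi} and \code{outOfRange}.
#' @examples
#' pPiEstimator(0.001, 0.00075)  # Qpi = 0.75, pPi = 0.5
#' @export
pPiEstimator <- function(piA, piX, r = 1) {
  if (any(piA <= 0)) stop("autosomal diversity must be > 0")
  Qpi <- (piX / piA) / r
  pPi <- 2 - 9 / (8 * Qpi)
  list(Qpi = Qpi, pPi = pPi, outOfRange = pPi <= 0 | pPi >= 1)
}

#' Bootstrap theta-ratio test for sex-bias
#'
#' The conventional test based on \eqn{\hat Q = \hat\theta_X /
#' (r\,\hat\theta_A)} (Watterson-style MLEs from the aggregate spectra)
#' with a percentile bootstrap over independent loci: the null of no
#' sex-bias is rejected when 0.75 falls outside the central
#' \eqn{1-\alpha} interval of the resampled \eqn{\hat Q}.
#'
#' @param lociA,lociX matrices of per-locus unfolded SFS counts (rows =
#'   loci, columns = frequency classes \eqn{1..n-1}).
#' @param LA,LX callable length per locus (bp).
#' @param iters bootstrap iterations.
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A}.
#' @param alpha test level.
#' @param seed optional RNG seed.
#' @return list with \code{Qhat}, \code{ci}, \code{reject}, \code{pPi}-style
#'   point estimate \code{pHat}, and the bootstrap replicates.
#' @export
qThetaTest <- function(lociA, lociX, LA = 1, LX = 1, iters = 1000, r = 1,
                       alpha = 0.05, seed = NULL) {
  lociA <- as.matrix(lociA); lociX <- as.matrix(lociX)
  if (nrow(lociA) < 2L || nrow(lociX) < 2L)
    stop("at least 2 independent loci per class are required to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  nA <- ncol(lociA) + 1L; nX <- ncol(lociX) + 1L
  HA <- expectedSFSConstant(nA)@sumF; HX <- expectedSFSConstant(nX)@sumF
  qhat <- function(ia, ix) {
    SA <- sum(lociA[ia, , drop = FALSE]); SX <- sum(lociX[ix, , drop = FALSE])
    thA <- SA / (HA * LA * length(ia)); thX <- SX / (HX * LX * length(ix))
    (thX / thA) / r
  }
  Q <- qhat(seq_len(nrow(lociA)), seq_len(nrow(lociX)))
  reps <- vapply(seq_len(iters), function(b) {
    qhat(sample.int(nrow(lociA), replace = TRUE),
         sample.int(nrow(lociX), replace = TRUE))
  }, numeric(1))
  ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(Qhat = Q, pHat = as.numeric(pFromQ(Q)), ci = ci,
       reject = 0.75 < ci[1] || 0.75 > ci[2], replicates = reps)
}
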