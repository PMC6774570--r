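# Closed-form two-sex Wright-Fisher relationships between the proportion of
# breeding females p, effective sizes, the X/autosome ratio Q, and the
# male/female mutation rate ratio alpha.

.P_EPS <- 1e-9

.checkP <- function(p) {
  if (any(!is.finite(p)) || any(p <= .P_EPS) || any(p >= 1 - .P_EPS))
    stop("p must lie strictly in (0, 1)")
  invisible(p)
}

#' Autosomal reduction factor f_A(p)
#'
#' The ratio of the autosomal inbreeding effective size to the census size
#' for a population with a proportion \code{p} of breeding females:
#' \eqn{f_A(p) = 4p(1-p)}. Maximal (1) at \code{p = 0.5} and symmetric
#' about it.
#'
#' @param p proportion of breeding females, in (0, 1).
#' @return dimensionless factor in (0, 1].
#' @examples
#' reductionFactorA(0.5)  # 1
#' reductionFactorA(0.2)  # 0.64
#' @export
reductionFactorA <- function(p) {
  .checkP(p)
  4 * p * (1 - p)
}

#' X-chromosomal reduction factor f_X(p)
#'
#' \eqn{f_X(p) = 9p(1-p) / (2(2-p))}: the ratio of the X-chromosomal
#' inbreeding effective size to the census size. Equals 0.75 at
#' \code{p = 0.5}.
#'
#' @inheritParams reductionFactorA
#' @return dimensionless factor in (0, 1).
#' @examples
#' reductionFactorX(0.5)  # 0.75
#' @export
reductionFactorX <- function(p) {
  .checkP(p)
  9 * p * (1 - p) / (2 * (2 - p))
}

#' X-to-autosome effective size ratio Q(p)
#'
#' \eqn{Q = N_{eX}/N_{eA} = 9 / (8(2-p))}, strictly increasing in \code{p};
#' 0.75 with no sex-bias and above 1 for \code{p > 0.875}.
#'
#' @inheritParams reductionFactorA
#' @return dimensionless ratio.
#' @examples
#' qRatio(0.5)  # 0.75
#' qRatio(0.4)  # 0.703125
#' @export
qRatio <- function(p) {
  .checkP(p)
  9 / (8 * (2 - p))
}

#' Invert Q to the proportion of females
#'
#' \eqn{p = 2 - 9/(8Q)}, the inverse of \code{\link{qRatio}} on (0, 1).
#' Estimates mapped from data may legitimately fall outside (0, 1) (for
#' example a negative value under a strong male bias combined with a
#' bottleneck); such values are returned as-is with a
#' \code{"outOfRange"} attribute rather than rejected, because they are
#' informative about model misspecification.
#'
#' @param Q X-to-autosome effective size ratio, > 0.
#' @return the implied proportion of females (possibly outside (0, 1)).
#' @examples
#' pFromQ(0.75)   # 0.5
#' pFromQ(1.0)    # 0.875
#' pFromQ(0.505)  # -0.2277...
#' @export
pFromQ <- function(Q) {
  if (any(!is.finite(Q)) || any(Q <= 0)) stop("Q must be > 0")
  p <- 2 - 9 / (8 * Q)
  attr(p, "outOfRange") <- p <= 0 | p >= 1
  p
}

#' X-chromosomal mutation rate from the male mutation bias
#'
#' Given the autosomal per-site rate and the male-to-female germline rate
#' ratio \eqn{\alpha = \mu_M/\mu_F}, the X rate is
#' \eqn{\mu_X = \mu_A \cdot 2(2+\alpha)/(3(1+\alpha))}, which decreases in
#' \eqn{\alpha} from \eqn{4/3\,\mu_A} (\eqn{\alpha = 0}) towards
#' \eqn{2/3\,\mu_A}.
#'
#' @param muA autosomal per-site per-generation mutation rate, > 0.
#' @param alpha male-to-female mutation rate ratio, >= 0.
#' @return the X-chromosomal per-site rate.
#' @examples
#' muXFromAlpha(1.2e-8, alpha = 3)  # (5/6) * 1.2e-8
#' @export
muXFromAlpha <- function(muA, alpha) {
  if (any(muA <= 0)) stop("muA must be > 0")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  muA * 2 * (2 + alpha) / (3 * (1 + alpha))
}

#' Mutation-rate ratio mu_X / mu_A implied by alpha
#'
#' @inheritParams muXFromAlpha
#' @return dimensionless ratio in (2/3, 4/3].
#' @export
muRatioFromAlpha <- function(alpha) muXFromAlpha(1, alpha)
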