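# Demographic model presets, the nested X-chromosomal constraint system
# (Models M0 / M1 / MT), and per-epoch sex-ratio recovery.

#' Demographic model presets
#'
#' Named epoch structures used throughout:
#' \describe{
#'   \item{constant}{single ancestral epoch.}
#'   \item{growth}{two epochs, instantaneous expansion. Defaults: 55-fold,
#'     205 generations ago, ancestral size 7,700 (a published European
#'     recent-growth model).}
#'   \item{growth_methods}{the smaller variant: ten-fold expansion 100
#'     generations ago, ancestral size 10,000.}
#'   \item{bottleneck}{three epochs. Defaults: ancestral 14,500; bottleneck
#'     to 1,861 from 2,040 to 920 generations ago; recovery to 100,000 (a
#'     simplified European Out-of-Africa history).}
#'   \item{bottlegrowth}{bottleneck followed by exponential growth.}
#'   \item{complex}{older instantaneous expansion, a bottleneck, then recent
#'     exponential growth.}
#' }
#'
#' @param name preset name.
#' @param params named list overriding preset defaults (absolute sizes in
#'   individuals, times in generations before present):
#'   \code{Nanc}; \code{nu}/\code{tGen} (growth); \code{NB}, \code{NF},
#'   \code{tStart}, \code{tEnd} (bottleneck-type); additionally
#'   \code{Nold}/\code{tOld} for \code{complex}.
#' @param generationTime years per generation (reporting only).
#' @return a \linkS4class{Demography}.
#' @examples
#' presetDemography("growth")
#' presetDemography("bottleneck")
#' @export
presetDemography <- function(name = c("constant", "growth", "growth_methods",
                                      "bottleneck", "bottlegrowth", "complex"),
                             params = list(), generationTime = 25) {
  name <- match.arg(name)
  dflt <- switch(name,
    constant = list(Nanc = 10000),
    growth = list(Nanc = 7700, nu = 55, tGen = 205),
    growth_methods = list(Nanc = 10000, nu = 10, tGen = 100),
    bottleneck = list(Nanc = 14500, NB = 1861, NF = 100000,
                      tStart = 2040, tEnd = 920),
    bottlegrowth = list(Nanc = 14500, NB = 1861, NF = 100000,
                        tStart = 2040, tEnd = 920),
    complex = list(Nanc = 7310, Nold = 14474, tOld = 5920,
                   NB = 1861, tStart = 2040, NF = 100000, tEnd = 920)
  )
  q <- utils::modifyList(dflt, params)
  switch(name,
    constant = demography(1, Inf, Nref = q$Nanc,
                          generationTime = generationTime),
    growth = ,
    growth_methods = demography(
      nu = c(1, q$nu), dur = c(Inf, q$tGen), Nref = q$Nanc,
      units = "generations", generationTime = generationTime),
    bottleneck = demography(
      nu = c(1, q$NB / q$Nanc, q$NF / q$Nanc),
      dur = c(Inf, q$tStart - q$tEnd, q$tEnd),
      Nref = q$Nanc, units = "generations",
      generationTime = generationTime),
    bottlegrowth = demography(
      nu = c(1, q$NB / q$Nanc, q$NF / q$Nanc),
      dur = c(Inf, q$tStart - q$tEnd, q$tEnd),
      change = c("instantaneous", "instantaneous", "exponential"),
      Nref = q$Nanc, units = "generations",
      generationTime = generationTime),
    complex = demography(
      nu = c(1, q$Nold / q$Nanc, q$NB / q$Nanc, q$NF / q$Nanc),
      dur = c(Inf, q$tOld - q$tStart, q$tStart - q$tEnd, q$tEnd),
      change = c("instantaneous", "instantaneous", "instantaneous",
                 "exponential"),
      Nref = q$Nanc, units = "generations",
      generationTime = generationTime)
  )
}

#' Derive the constrained X-chromosomal demography from an autosomal one
#'
#' Implements the epoch-size invariant \eqn{N_{tX} = Q(p_t) N_{tA}} with all
#' size-change events at the same times in generations. In the X
#' chromosome's own coalescent units (of \eqn{2 N_{refX}} with
#' \eqn{N_{refX} = Q(p_1) N_{refA}}) this yields
#' \eqn{\nu_{tX} = Q(p_t)/Q(p_1)\,\nu_{tA}} and
#' \eqn{\tau_{tX} = \tau_{tA}/Q(p_1)}, and a per-site
#' \eqn{\theta_X = Q(p_1)\, r\, \theta_A}. With all \eqn{p_t = 0.5} this is
#' the classical no-sex-bias constraint (\eqn{\nu_X = \nu_A},
#' \eqn{\tau_X = 4/3\,\tau_A}, \eqn{\theta_X = 3/4\, r\, \theta_A}); a single
#' shared \eqn{p} gives the constant-bias model; per-epoch \eqn{p_t} the
#' changing-bias model.
#'
#' @param auto autosomal \linkS4class{Demography}.
#' @param p per-epoch proportion of females (recycled to the number of
#'   epochs).
#' @param r mutation-rate ratio \eqn{\mu_X/\mu_A}.
#' @return list with components \code{dem} (the X
#'   \linkS4class{Demography}), \code{NrefX} (\code{NA} if the autosomal
#'   model has no absolute anchor), and \code{thetaScale} such that
#'   \eqn{\theta_X = thetaScale \cdot \theta_A} per site.
#' @export
deriveXDemography <- function(auto, p, r = 1) {
  stopifnot(is(auto, "Demography"))
  T <- nEpochs(auto)
  p <- rep_len(p, T)
  .checkP(p)
  qs <- qRatio(p)
  ep <- epochs(auto)
  nuX <- qs / qs[1] * ep$nu
  durX <- ep$dur / qs[1]
  demX <- new("Demography",
              epochs = data.frame(nu = nuX, dur = durX, change = ep$change,
                                  stringsAsFactors = FALSE),
              Nref = qs[1] * auto@Nref,
              generationTime = auto@generationTime)
  validObject(demX)
  list(dem = demX, NrefX = qs[1] * auto@Nref, thetaScale = qs[1] * r)
}

#' Per-epoch sex-ratio estimates from fitted effective sizes
#'
#' \eqn{\tilde p_t = 2 - 9 N_{etA} / (8 N_{etX})}: the inversion of the
#' X-to-autosome size ratio, applied epoch by epoch. Values outside (0, 1)
#' are returned as-is (see \code{\link{pFromQ}}).
#'
#' @param NeA,NeX per-epoch autosomal and X-chromosomal effective sizes
#'   (positive, equal length).
#' @return numeric vector of per-epoch estimates.
#' @examples
#' pPerEpochFromFit(c(10000, 2000), c(7500, 1500))  # 0.5, 0.5
#' @export
pPerEpochFromFit <- function(NeA, NeX) {
  if (length(NeA) != length(NeX)) stop("NeA and NeX must have equal length")
  if (any(NeA <= 0) || any(NeX <= 0)) stop("effective sizes must be > 0")
  as.numeric(pFromQ(NeX / NeA))
}

#' Scale a census demography into a sex-specific locus-class demography
#'
#' For simulation: given a census trajectory \eqn{N_t} and per-epoch
#' proportions of females \eqn{p_t}, the autosomal class evolves with sizes
#' \eqn{f_A(p_t) N_t} and the X class with \eqn{f_X(p_t) N_t}.
#'
#' @param census a \linkS4class{Demography} with absolute \code{Nref}.
#' @param p per-epoch proportion of females (recycled).
#' @param class \code{"autosome"} or \code{"X"}.
#' @return a \linkS4class{Demography} for the locus class, anchored at its
#'   own ancestral effective size.
#' @export
scaleDemographyBySex <- function(census, p, class = c("autosome", "X")) {
  class <- match.arg(class)
  stopifnot(is(census, "Demography"))
  if (is.na(census@Nref)) stop("census demography must have an absolute Nref")
  T <- nEpochs(census)
  p <- rep_len(p, T)
  f <- if (class == "autosome") reductionFactorA(p) else reductionFactorX(p)
  ep <- epochs(census)
  Nt <- ep$nu * census@Nref
  Ncls <- f * Nt
  new("Demography",
      epochs = data.frame(nu = Ncls / Ncls[1],
                          dur = ep$dur * census@Nref / Ncls[1],
                          change = ep$change, stringsAsFactors = FALSE),
      Nref = Ncls[1], generationTime = census@generationTime)
}
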