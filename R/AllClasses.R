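#' @import methods
NULL

#' SpectrumData: a site frequency spectrum with metadata
#'
#' Container for an observed or simulated site frequency spectrum (SFS).
#' Unfolded spectra hold the polymorphic classes \eqn{i = 1, \ldots, n-1}
#' (derived-allele counts); folded spectra hold minor-allele classes
#' \eqn{i = 1, \ldots, \lfloor n/2 \rfloor}. Monomorphic classes are never
#' stored. The mask flags entries to be excluded from likelihoods.
#'
#' @slot counts numeric vector of per-class segregating-site counts.
#' @slot n integer, number of sampled chromosomes.
#' @slot folded logical, whether the spectrum is folded.
#' @slot mask logical vector, \code{TRUE} = excluded from likelihoods.
#' @slot L numeric, callable locus length in base pairs.
#' @slot mu numeric, per-site per-generation mutation rate (may be \code{NA}).
#' @slot chromClass character, \code{"autosome"} or \code{"X"}.
#'
#' @export
setClass("SpectrumData",
  representation(
    counts = "numeric",
    n = "integer",
    folded = "logical",
    mask = "logical",
    L = "numeric",
    mu = "numeric",
    chromClass = "character"
  )
)

setValidity("SpectrumData", function(object) {
  msgs <- character(0)
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 2L)
    msgs <- c(msgs, "n must be a single integer >= 2")
  expLen <- if (isTRUE(object@folded)) n %/% 2L else n - 1L
  if (length(object@counts) != expLen)
    msgs <- c(msgs, sprintf("counts must have length %d (%s, n = %d)",
                            expLen, if (object@folded) "folded" else "unfolded", n))
  if (length(object@mask) != length(object@counts))
    msgs <- c(msgs, "mask length must equal counts length")
  unmasked <- object@counts[!object@mask]
  if (any(is.na(unmasked)) || any(unmasked < 0))
    msgs <- c(msgs, "unmasked counts must be non-negative")
  if (!(length(object@L) == 1L && !is.na(object@L) && object@L > 0))
    msgs <- c(msgs, "L must be a single positive number")
  if (!object@chromClass %in% c("autosome", "X"))
    msgs <- c(msgs, "chromClass must be 'autosome' or 'X'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectrumData object
#'
#' @param counts numeric vector of polymorphic-class counts
#'   (length \code{n-1} unfolded, \code{floor(n/2)} folded).
#' @param n number of sampled chromosomes.
#' @param folded logical; is the spectrum folded?
#' @param mask optional logical vector of masked entries (default none).
#' @param L callable locus length in bp (default 1, i.e. counts are per-locus).
#' @param mu per-site per-generation mutation rate, or \code{NA}.
#' @param chromClass \code{"autosome"} or \code{"X"}.
#' @return a \linkS4class{SpectrumData} object.
#' @examples
#' spectrumData(c(5, 2, 1), n = 4)
#' @export
spectrumData <- function(counts, n, folded = FALSE, mask = NULL, L = 1,
                         mu = NA_real_, chromClass = c("autosome", "X")) {
  chromClass <- match.arg(chromClass)
  if (is.null(mask)) mask <- rep(FALSE, length(counts))
  new("SpectrumData", counts = as.numeric(counts), n = as.integer(n),
      folded = as.logical(folded), mask = as.logical(mask),
      L = as.numeric(L), mu = as.numeric(mu), chromClass = chromClass)
}

#' Demography: a multi-epoch demographic model
#'
#' Epochs are ordered oldest to newest; the first epoch is the ancestral
#' equilibrium (relative size fixed at 1). Each later epoch has a relative
#' size \code{nu} (size at the epoch end relative to the ancestral size), a
#' duration, and a change type. With \code{change = "instantaneous"} the size
#' is \code{nu} throughout the epoch; with \code{"exponential"} the size moves
#' exponentially from the previous epoch's \code{nu} to this epoch's
#' \code{nu} across the epoch. Durations are stored in coalescent units of
#' \eqn{2 N_{ref}} generations, where \eqn{N_{ref}} is the ancestral size.
#'
#' @slot epochs data.frame with columns \code{nu}, \code{dur} (coalescent
#'   units; \code{Inf} for the ancestral epoch) and \code{change}.
#' @slot Nref ancestral absolute size in individuals (\code{NA} if the model
#'   is purely relative).
#' @slot generationTime years per generation, used only for reporting.
#' @export
setClass("Demography",
  representation(
    epochs = "data.frame",
    Nref = "numeric",
    generationTime = "numeric"
  )
)

setValidity("Demography", function(object) {
  ep <- object@epochs
  msgs <- character(0)
  if (!all(c("nu", "dur", "change") %in% names(ep)))
    msgs <- c(msgs, "epochs must have columns nu, dur, change")
  else {
    if (nrow(ep) < 1L) msgs <- c(msgs, "at least one epoch is required")
    if (nrow(ep) >= 1L && abs(ep$nu[1] - 1) > 1e-12)
      msgs <- c(msgs, "the first (ancestral) epoch must have nu = 1")
    if (any(ep$nu <= 0)) msgs <- c(msgs, "relative sizes nu must be > 0")
    if (nrow(ep) > 1L && any(ep$dur[-1] <= 0))
      msgs <- c(msgs, "epoch durations must be > 0")
    if (!all(ep$change %in% c("instantaneous", "exponential")))
      msgs <- c(msgs, "change must be 'instantaneous' or 'exponential'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Demography
#'
#' @param nu numeric vector of relative epoch-end sizes, oldest to newest;
#'   the first entry must be 1 (the ancestral size).
#' @param dur epoch durations, oldest to newest; the first entry is ignored
#'   (the ancestral epoch extends indefinitely into the past).
#' @param change per-epoch change type, recycled; \code{"instantaneous"} or
#'   \code{"exponential"}.
#' @param Nref ancestral absolute size in individuals (optional).
#' @param units units of \code{dur}: \code{"generations"} (converted using
#'   \code{Nref}) or \code{"coalescent"} (units of \eqn{2 N_{ref}}).
#' @param generationTime years per generation (reporting only).
#' @return a \linkS4class{Demography}.
#' @examples
#' ## 55-fold instantaneous expansion 205 generations ago
#' demography(nu = c(1, 55), dur = c(Inf, 205), Nref = 7700,
#'            units = "generations")
#' @export
demography <- function(nu, dur, change = "instantaneous", Nref = NA_real_,
                       units = c("coalescent", "generations"),
                       generationTime = 25) {
  units <- match.arg(units)
  k <- length(nu)
  change <- rep_len(change, k)
  dur <- as.numeric(dur)
  if (units == "generations") {
    if (is.na(Nref)) stop("Nref is required to convert generations to coalescent units")
    dur <- dur / (2 * Nref)
  }
  dur[1] <- Inf
  new("Demography",
      epochs = data.frame(nu = as.numeric(nu), dur = dur,
                          change = as.character(change),
                          stringsAsFactors = FALSE),
      Nref = as.numeric(Nref), generationTime = as.numeric(generationTime))
}

#' SFSDensity: expected per-theta SFS density
#'
#' The vector \eqn{F(i)} such that the expected count in frequency class
#' \eqn{i} is \eqn{\theta L F(i)} with \eqn{\theta = 4 N_{ref} \mu} per site.
#' Under a constant-size demography \eqn{F(i) = 1/i} exactly.
#'
#' @slot F numeric vector of per-class densities.
#' @slot sumF their sum (the Watterson denominator).
#' @slot n sample size in chromosomes.
#' @slot folded logical.
#' @export
setClass("SFSDensity",
  representation(F = "numeric", sumF = "numeric", n = "integer",
                 folded = "logical")
)

setValidity("SFSDensity", function(object) {
  if (any(object@F < 0)) return("F entries must be non-negative")
  TRUE
})

#' FitResult: a fitted demographic model
#'
#' @slot model the fitted \linkS4class{Demography}.
#' @slot theta per-site population-scaled mutation rate MLE.
#' @slot loglik maximized Poisson log-likelihood. For X-chromosomal
#'   constrained fits this is the joint autosomal + X log-likelihood.
#' @slot converged logical.
#' @slot trace list of optimizer diagnostics (restarts, bound hits, grid).
#' @slot pEstimates per-epoch estimates of the proportion of females (empty
#'   for autosomal fits).
#' @slot level character: \code{"A"} for autosomal fits, else
#'   \code{"M0"}, \code{"M1"} or \code{"MT"}.
#' @export
setClass("FitResult",
  representation(
    model = "Demography",
    theta = "numeric",
    loglik = "numeric",
    converged = "logical",
    trace = "list",
    pEstimates = "numeric",
    level = "character"
  )
)

#' SexBiasTestResult: nested likelihood-ratio tests for sex-bias
#'
#' @slot loglik named numeric of joint model log-likelihoods.
#' @slot lambda named numeric of LRT statistics.
#' @slot df degrees of freedom per comparison.
#' @slot pvalue chi-square p-values per comparison.
#' @slot critical critical value(s) used.
#' @slot criticalSource provenance: \code{"chisq"}, \code{"empirical"} or
#'   \code{"parametric"}.
#' @slot reject logical per comparison.
#' @slot pEstimates list of per-model sex-ratio estimates.
#' @export
setClass("SexBiasTestResult",
  representation(
    loglik = "numeric",
    lambda = "numeric",
    df = "numeric",
    pvalue = "numeric",
    critical = "numeric",
    criticalSource = "character",
    reject = "logical",
    pEstimates = "list"
  )
)

setMethod("show", "SpectrumData", function(object) {
  cat(sprintf("SpectrumData: %s, n = %d chromosomes, %s\n",
              object@chromClass, object@n,
              if (object@folded) "folded" else "unfolded"))
  cat(sprintf("  classes: %d (%d masked), segregating sites: %s\n",
              length(object@counts), sum(object@mask),
              format(sum(object@counts[!object@mask]))))
  cat(sprintf("  L = %s bp, mu = %s\n", format(object@L), format(object@mu)))
})

setMethod("show", "Demography", function(object) {
  ep <- object@epochs
  cat(sprintf("Demography: %d epoch(s), Nref = %s\n", nrow(ep),
              format(object@Nref)))
  for (t in seq_len(nrow(ep))) {
    cat(sprintf("  epoch %d: nu = %.4g, dur = %.4g (2Nref gens), %s\n",
                t, ep$nu[t], ep$dur[t], ep$change[t]))
  }
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]: loglik = %.4f, theta/site = %.4g, converged: %s\n",
              object@level, object@loglik, object@theta, object@converged))
  if (length(object@pEstimates))
    cat("  p per epoch:", paste(sprintf("%.3f", object@pEstimates),
                                collapse = ", "), "\n")
})

setMethod("show", "SexBiasTestResult", function(object) {
  cat("Sex-bias likelihood ratio test\n")
  cat("  log-likelihoods:",
      paste(sprintf("%s = %.3f", names(object@loglik), object@loglik),
            collapse = ", "), "\n")
  for (i in seq_along(object@lambda)) {
    cat(sprintf("  %s = %.4f (df = %d, p = %.3g, critical = %.3f [%s], %s)\n",
                names(object@lambda)[i], object@lambda[i], object@df[i],
                object@pvalue[i], object@critical[i], object@criticalSource,
                if (object@reject[i]) "reject" else "accept"))
  }
})
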