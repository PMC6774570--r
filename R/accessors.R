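# Accessor generics and methods for the core classes.

#' @name accessors
#' @title Accessors for SpectrumData and Demography
#' @description Slot accessors; user code should prefer these over `@`.
#' @param x a \linkS4class{SpectrumData} or \linkS4class{Demography}.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))
#' @rdname accessors
#' @export
setMethod("sfsCounts", "SpectrumData", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))
#' @rdname accessors
#' @export
setMethod("sampleSize", "SpectrumData", function(x) x@n)

#' @rdname accessors
#' @export
setGeneric("isFolded", function(x) standardGeneric("isFolded"))
#' @rdname accessors
#' @export
setMethod("isFolded", "SpectrumData", function(x) x@folded)

#' @rdname accessors
#' @export
setGeneric("sfsMask", function(x) standardGeneric("sfsMask"))
#' @rdname accessors
#' @export
setMethod("sfsMask", "SpectrumData", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("locusLength", function(x) standardGeneric("locusLength"))
#' @rdname accessors
#' @export
setMethod("locusLength", "SpectrumData", function(x) x@L)

#' @rdname accessors
#' @export
setGeneric("mutationRate", function(x) standardGeneric("mutationRate"))
#' @rdname accessors
#' @export
setMethod("mutationRate", "SpectrumData", function(x) x@mu)

#' @rdname accessors
#' @export
setGeneric("chromClass", function(x) standardGeneric("chromClass"))
#' @rdname accessors
#' @export
setMethod("chromClass", "SpectrumData", function(x) x@chromClass)

#' Total number of segregating sites (unmasked classes)
#' @param x a \linkS4class{SpectrumData}.
#' @return numeric count.
#' @export
setGeneric("segSites", function(x) standardGeneric("segSites"))
#' @rdname segSites
#' @export
setMethod("segSites", "SpectrumData", function(x) sum(x@counts[!x@mask]))

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setMethod("epochs", "Demography", function(x) x@epochs)

#' @rdname accessors
#' @export
setGeneric("ancestralSize", function(x) standardGeneric("ancestralSize"))
#' @rdname accessors
#' @export
setMethod("ancestralSize", "Demography", function(x) x@Nref)

#' Number of epochs of a demographic model
#' @param x a \linkS4class{Demography}.
#' @return integer.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname nEpochs
#' @export
setMethod("nEpochs", "Demography", function(x) nrow(x@epochs))

#' Absolute effective size at the end of each epoch
#'
#' Requires \code{Nref} to be set.
#' @param x a \linkS4class{Demography}.
#' @return numeric vector, oldest to newest.
#' @export
setGeneric("epochSizes", function(x) standardGeneric("epochSizes"))
#' @rdname epochSizes
#' @export
setMethod("epochSizes", "Demography", function(x) {
  if (is.na(x@Nref)) stop("Nref is not set; absolute sizes are unresolved")
  x@epochs$nu * x@Nref
})

#' Epoch start times in generations before present
#'
#' The ancestral epoch has no start (\code{Inf}). Requires \code{Nref}.
#' @param x a \linkS4class{Demography}.
#' @return numeric vector, oldest to newest; the last entry is the time of
#'   the most recent size change.
#' @export
setGeneric("epochStartGen", function(x) standardGeneric("epochStartGen"))
#' @rdname epochStartGen
#' @export
setMethod("epochStartGen", "Demography", function(x) {
  if (is.na(x@Nref)) stop("Nref is not set; times in generations are unresolved")
  dur <- x@epochs$dur * 2 * x@Nref
  k <- length(dur)
  if (k == 1L) return(Inf)
  ## backward-time start of epoch t = sum of durations of epochs t..k
  starts <- rev(cumsum(rev(dur[-1])))
  c(Inf, starts)
})
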