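# Expected site frequency spectra under multi-epoch demographies.
#
# The engine is exact for the neutral one-population SFS: the ancestral
# lineage-count process of a sample of n chromosomes is a pure-death Markov
# chain with rate k(k-1)/2 / nu(t) (time in units of 2*Nref generations).
# Expected occupation times E[t_k] are computed by uniformization within each
# constant-size piece (exponential epochs are discretized internally), with
# the ancestral equilibrium epoch handled in closed form. The per-theta
# density is then
#   F(b) = 1/2 * sum_k  k E[t_k] P(b | k),
# where P(b | k) = C(n-b-1, k-2) / C(n-1, k-1) is the probability that a
# lineage present when k lineages remain subtends b of the n samples.
# Under constant size E[t_k] = 2/(k(k-1)) and F(b) = 1/b exactly.

.wCache <- new.env(parent = emptyenv())

# W[b, k] = P(a level-k lineage subtends b leaves), b = 1..n-1, k = 2..n
.subtendMatrix <- function(n) {
  key <- as.character(n)
  W <- .wCache[[key]]
  if (!is.null(W)) return(W)
  b <- seq_len(n - 1L)
  k <- 2:n
  W <- exp(outer(b, k, function(b, k)
    lchoose(n - b - 1, k - 2) - lchoose(n - 1, k - 1)))
  W[!is.finite(W)] <- 0
  .wCache[[key]] <- W
  W
}

# Piecewise-constant backward-time representation: data.frame(nu, s) ordered
# from the present backwards, excluding the (infinite) ancestral epoch.
.backwardPieces <- function(dem, nExpSub = 32L) {
  ep <- epochs(dem)
  k <- nrow(ep)
  if (k == 1L) return(data.frame(nu = numeric(0), s = numeric(0)))
  pieces <- vector("list", k - 1L)
  for (t in k:2) {
    if (ep$change[t] == "instantaneous") {
      pieces[[k - t + 1L]] <- data.frame(nu = ep$nu[t], s = ep$dur[t])
    } else {
      ## size moves exponentially from nu[t-1] (old edge) to nu[t] (recent
      ## edge); u is backward time within the epoch measured from the
      ## recent edge
      d <- ep$dur[t]
      u <- (seq_len(nExpSub) - 0.5) / nExpSub * d
      nuU <- ep$nu[t] * (ep$nu[t - 1L] / ep$nu[t])^(u / d)
      pieces[[k - t + 1L]] <- data.frame(nu = nuU, s = rep(d / nExpSub, nExpSub))
    }
  }
  do.call(rbind, pieces)
}

# Advance the lineage-count distribution p through a constant-size piece of
# duration s, accumulating expected occupation times into e. cc = k(k-1)/2.
.advanceConstant <- function(p, e, nu, s, cc, maxChunks = 5000L) {
  nchunk <- 0L
  while (s > 0) {
    sup <- which(p > 1e-14)
    kmax <- if (length(sup)) max(sup) else 1L
    if (kmax == 1L) break
    if (kmax == 2L) {
      ## exact two-state solution
      r <- cc[2L] / nu
      surv <- exp(-r * s)
      e[2L] <- e[2L] + p[2L] * (1 - surv) / r
      p[1L] <- p[1L] + p[2L] * (1 - surv)
      p[2L] <- p[2L] * surv
      break
    }
    nchunk <- nchunk + 1L
    if (nchunk > maxChunks)
      stop(sprintf(paste0("expected-SFS solver failed to converge ",
                          "(nu = %g, residual duration = %g, kmax = %d)"),
                   nu, s, kmax))
    lam <- cc[kmax] / nu
    schunk <- min(s, 400 / lam)
    ls <- lam * schunk
    K <- as.integer(ceiling(ls + 12 * sqrt(ls + 1) + 25))
    dp <- stats::dpois(0:K, ls)
    tp <- stats::ppois(0:K, ls, lower.tail = FALSE)
    ratio <- cc[seq_len(kmax)] / (lam * nu)
    piJ <- p[seq_len(kmax)]
    inflow <- c(ratio[-1L], 0)
    pend <- dp[1L] * piJ
    eacc <- tp[1L] * piJ
    for (j in seq_len(K)) {
      piJ <- piJ * (1 - ratio) + c(piJ[-1L], 0) * inflow
      pend <- pend + dp[j + 1L] * piJ
      eacc <- eacc + tp[j + 1L] * piJ
    }
    e[seq_len(kmax)] <- e[seq_len(kmax)] + eacc / lam
    pend[pend < 0] <- 0
    p[seq_len(kmax)] <- pend / sum(pend) * sum(p[seq_len(kmax)])
    s <- s - schunk
  }
  list(p = p, e = e)
}

# Expected occupation times E[t_k], k = 1..n, in units of 2*Nref generations.
.coalTimes <- function(dem, n) {
  cc <- choose(seq_len(n), 2)  # cc[k] = k(k-1)/2
  p <- numeric(n); p[n] <- 1
  e <- numeric(n)
  pieces <- .backwardPieces(dem)
  for (i in seq_len(nrow(pieces))) {
    st <- .advanceConstant(p, e, pieces$nu[i], pieces$s[i], cc)
    p <- st$p; e <- st$e
  }
  ## ancestral equilibrium epoch (nu = 1): a lineage count >= k implies the
  ## chain passes through state k, spending Exp(k(k-1)/2) there
  pGE <- rev(cumsum(rev(p)))
  k2 <- 2:n
  e[k2] <- e[k2] + pGE[k2] / cc[k2]
  e
}

#' Expected SFS density for a constant-size population
#'
#' Under the Poisson random field model at equilibrium the expected count in
#' derived-allele class \eqn{i} is \eqn{\theta L / i}, so \eqn{F(i) = 1/i}.
#'
#' @param n number of sampled chromosomes, >= 2.
#' @return an \linkS4class{SFSDensity}.
#' @examples
#' expectedSFSConstant(4)  # F = 1, 1/2, 1/3
#' @export
expectedSFSConstant <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2")
  F <- 1 / seq_len(n - 1L)
  new("SFSDensity", F = F, sumF = sum(F), n = n, folded = FALSE)
}

#' Expected SFS density under a multi-epoch demography
#'
#' Computes the exact expected per-theta site frequency spectrum for a
#' sample of \code{n} chromosomes under the given demographic model, via the
#' expected occupation times of the ancestral lineage-count chain
#' (uniformization) and the subtended-leaf combinatorics. The expected count
#' in class \eqn{i} for a locus is \eqn{\theta L F(i)} with
#' \eqn{\theta = 4 N_{ref} \mu} per site.
#'
#' @param dem a \linkS4class{Demography}.
#' @param n number of sampled chromosomes, >= 2.
#' @param folded return the folded density?
#' @return an \linkS4class{SFSDensity}.
#' @examples
#' d <- demography(nu = c(1, 10), dur = c(Inf, 0.05))
#' expectedSFS(d, n = 10)
#' @export
expectedSFS <- function(dem, n, folded = FALSE) {
  stopifnot(is(dem, "Demography"))
  validObject(dem)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2")
  e <- .coalTimes(dem, n)
  W <- .subtendMatrix(n)
  F <- as.vector(0.5 * W %*% ((2:n) * e[2:n]))
  F[F < 0] <- 0
  dens <- new("SFSDensity", F = F, sumF = sum(F), n = n, folded = FALSE)
  if (folded) foldSFS(dens) else dens
}

#' Fold a site frequency spectrum
#'
#' Combines derived-allele classes \eqn{i} and \eqn{n-i} into minor-allele
#' classes: \code{folded[i] = counts[i] + counts[n-i]} for \eqn{i < n/2},
#' with the central class kept as-is for even \eqn{n}. The total number of
#' segregating sites is conserved. Masks are combined with OR.
#'
#' @param x an unfolded \linkS4class{SpectrumData} or
#'   \linkS4class{SFSDensity}.
#' @return the folded object of the same class.
#' @examples
#' foldSFS(spectrumData(c(3, 2, 1), n = 4))  # counts 4, 2
#' @export
setGeneric("foldSFS", function(x) standardGeneric("foldSFS"))

.foldVector <- function(v, n) {
  h <- n %/% 2L
  out <- numeric(h)
  for (i in seq_len(h)) {
    out[i] <- if (i < n - i) v[i] + v[n - i] else v[i]
  }
  out
}

#' @rdname foldSFS
#' @export
setMethod("foldSFS", "SpectrumData", function(x) {
  if (isFolded(x)) stop("spectrum is already folded")
  n <- sampleSize(x)
  h <- n %/% 2L
  m <- logical(h)
  for (i in seq_len(h))
    m[i] <- if (i < n - i) x@mask[i] || x@mask[n - i] else x@mask[i]
  spectrumData(.foldVector(sfsCounts(x), n), n = n, folded = TRUE, mask = m,
               L = locusLength(x), mu = mutationRate(x),
               chromClass = chromClass(x))
})

#' @rdname foldSFS
#' @export
setMethod("foldSFS", "SFSDensity", function(x) {
  if (x@folded) stop("density is already folded")
  F <- .foldVector(x@F, x@n)
  new("SFSDensity", F = F, sumF = sum(F), n = x@n, folded = TRUE)
})

#' Hypergeometric projection to a smaller sample size
#'
#' Projects an unfolded spectrum from \code{n} to \code{m} chromosomes:
#' the expected count in class \eqn{j} of the smaller sample is
#' \eqn{\sum_i counts_i \, C(i,j) C(n-i, m-j) / C(n,m)}, accumulated over
#' the polymorphic classes \eqn{1 \le j \le m-1}. Mass projected into the
#' monomorphic classes (\eqn{j = 0} or \eqn{j = m}) is dropped; the dropped
#' amount is attached as attribute \code{"droppedMass"} and reported via a
#' message.
#'
#' @param x an unfolded \linkS4class{SpectrumData} with no masked entries.
#' @param m target number of chromosomes, \code{2 <= m <= n}.
#' @return a \linkS4class{SpectrumData} on \code{m} chromosomes
#'   (\code{m = n} returns the input unchanged).
#' @export
projectSFS <- function(x, m) {
  stopifnot(is(x, "SpectrumData"))
  if (isFolded(x)) stop("projection operates on unfolded spectra; unfold first")
  n <- sampleSize(x)
  m <- as.integer(m)
  if (m > n) stop("cannot project up: m must be <= n")
  if (m < 2L) stop("m must be >= 2")
  if (any(sfsMask(x))) stop("projection requires an unmasked spectrum")
  if (m == n) return(x)
  i <- seq_len(n - 1L)
  j <- 0:m
  ## P[i, j+1] = C(i, j) C(n-i, m-j) / C(n, m)
  P <- exp(outer(i, j, function(i, j)
    lchoose(i, j) + lchoose(n - i, m - j) - lchoose(n, m)))
  P[!is.finite(P)] <- 0
  proj <- as.vector(sfsCounts(x) %*% P)
  dropped <- proj[1L] + proj[m + 1L]
  out <- spectrumData(proj[2:m], n = m, folded = FALSE,
                      L = locusLength(x), mu = mutationRate(x),
                      chromClass = chromClass(x))
  attr(out, "droppedMass") <- dropped
  if (dropped > 0)
    message(sprintf("projection to %d chromosomes dropped %.4g expected sites into monomorphic classes",
                    m, dropped))
  out
}

#' Watterson denominator: the summed SFS density
#'
#' \eqn{\sum_{i=1}^{n-1} F(i)} for the active demography; with constant
#' size this is the harmonic number \eqn{H_{n-1}}, the denominator of the
#' Watterson estimator.
#'
#' @param n number of sampled chromosomes, >= 2.
#' @param dem optional \linkS4class{Demography}; \code{NULL} means constant
#'   size.
#' @return numeric scalar.
#' @examples
#' wattersonSum(5)  # 1 + 1/2 + 1/3 + 1/4
#' @export
wattersonSum <- function(n, dem = NULL) {
  if (is.null(dem)) expectedSFSConstant(n)@sumF else expectedSFS(dem, n)@sumF
}
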