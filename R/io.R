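# SFS file dialect, VCF -> SFS construction, callable-length bookkeeping.
#
# SFS text dialect: line 1 is "<n+1> <folded|unfolded>", line 2 the n+1
# per-class counts including the two monomorphic classes, line 3 a 0/1 mask
# (1 = masked). Folded files must have zero counts above floor(n/2).

#' Write a spectrum to an SFS text file
#'
#' @param s a \linkS4class{SpectrumData}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSFS <- function(s, path) {
  stopifnot(is(s, "SpectrumData"))
  n <- sampleSize(s)
  full <- numeric(n + 1L)
  fullMask <- rep(1L, n + 1L)
  idx <- if (isFolded(s)) seq_len(n %/% 2L) else seq_len(n - 1L)
  full[idx + 1L] <- sfsCounts(s)
  fullMask[idx + 1L] <- as.integer(sfsMask(s))
  lines <- c(
    sprintf("%d %s", n + 1L, if (isFolded(s)) "folded" else "unfolded"),
    paste(format(full, trim = TRUE, scientific = FALSE), collapse = " "),
    paste(fullMask, collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrum from an SFS text file
#'
#' @param path input file path.
#' @param L callable locus length to attach (bp; not stored in the file).
#' @param mu per-site mutation rate to attach.
#' @param chromClass \code{"autosome"} or \code{"X"}.
#' @return a \linkS4class{SpectrumData}.
#' @export
readSFS <- function(path, L = 1, mu = NA_real_,
                    chromClass = c("autosome", "X")) {
  chromClass <- match.arg(chromClass)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("malformed SFS file (expected 3 lines): ", path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || !hdr[2L] %in% c("folded", "unfolded"))
    stop("line 1: expected '<dim> <folded|unfolded>'")
  dim <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(dim) || dim < 3L) stop("line 1: invalid dimension token")
  n <- dim - 1L
  folded <- hdr[2L] == "folded"
  counts <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]]))
  if (length(counts) != dim)
    stop(sprintf("line 2: expected %d count tokens, found %d", dim,
                 length(counts)))
  if (any(is.na(counts)) || any(counts < 0))
    stop("line 2: counts must be non-negative numbers")
  mask <- suppressWarnings(as.integer(strsplit(trimws(lines[3L]), "\\s+")[[1L]]))
  if (length(mask) != dim)
    stop(sprintf("line 3: expected %d mask tokens, found %d", dim,
                 length(mask)))
  if (any(is.na(mask)) || !all(mask %in% 0:1))
    stop("line 3: mask tokens must be 0 or 1")
  if (folded) {
    h <- n %/% 2L
    if (any(counts[(h + 2L):(n + 1L)] != 0))
      stop("folded spectrum has non-zero entries above n/2")
    idx <- seq_len(h)
  } else {
    idx <- seq_len(n - 1L)
  }
  spectrumData(counts[idx + 1L], n = n, folded = folded,
               mask = as.logical(mask[idx + 1L]), L = L, mu = mu,
               chromClass = chromClass)
}

# Normalize a genotype string to allele integers; half-calls become fully
# missing. Returns an integer vector of length ploidy (all-NA when
# missing), or NULL for a fully missing call of unknown ploidy.
.gtAlleles <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  a <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1L]]))
  if (any(is.na(a))) return(rep(NA_integer_, length(a)))  # half-call
  a
}

#' Build a site frequency spectrum from a VCF
#'
#' Retains biallelic SNPs only; sets half-calls to missing; excludes sites
#' with more than \code{maxMissing} missing genotypes; optionally excludes
#' regions via a BED-style data.frame (0-based half-open); handles residual
#' missingness by hypergeometric projection of every site to a common
#' number of called chromosomes; folds by default (no ancestral allele
#' needed). The callable length is adjusted by the fraction of SNPs
#' surviving the filters (and again by the mass retained after projection).
#'
#' For X-chromosomal input all samples must have the same ploidy at every
#' site (e.g. diploid females); mixed-ploidy calls are an error rather than
#' a silent miscount.
#'
#' @param vcfPath path to a VCF file (plain or bgzipped).
#' @param samples optional character vector of sample names to keep.
#' @param chromClass \code{"autosome"} or \code{"X"}.
#' @param fold fold the spectrum (default \code{TRUE})?
#' @param maxMissing maximum fraction of missing genotypes per site.
#' @param project target number of chromosomes (default: the minimum number
#'   of called chromosomes across retained sites).
#' @param excludeBed optional data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) of regions to exclude.
#' @param rawLength raw callable length of the locus in bp.
#' @param mu per-site mutation rate to attach.
#' @return list with \code{sfs} (a \linkS4class{SpectrumData}),
#'   \code{callable} (raw length, retained fraction, adjusted length) and
#'   \code{log} (per-filter site counts).
#' @export
vcfToSFS <- function(vcfPath, samples = NULL,
                     chromClass = c("autosome", "X"), fold = TRUE,
                     maxMissing = 0.05, project = NULL, excludeBed = NULL,
                     rawLength, mu = NA_real_) {
  chromClass <- match.arg(chromClass)
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  if (!is.null(samples)) {
    missingSamp <- setdiff(samples, colnames(gt))
    if (length(missingSamp))
      stop("samples not in VCF: ", paste(missingSamp, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  nSitesTotal <- nrow(fix)

  alt <- fix[, "ALT"]; ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nBiallelic <- sum(biallelic)
  if (nBiallelic == 0L) {
    warning("no biallelic SNPs in VCF; returning an empty spectrum")
    m <- if (is.null(project)) 2L * ncol(gt) else as.integer(project)
    len <- if (fold) m %/% 2L else m - 1L
    return(list(sfs = spectrumData(numeric(len), n = m, folded = fold,
                                   L = rawLength, mu = mu,
                                   chromClass = chromClass),
                callable = list(raw = rawLength, retainedFraction = 1,
                                adjusted = rawLength),
                log = list(nSitesTotal = nSitesTotal, nBiallelic = 0L,
                           nExcludedBed = 0L, nFilteredMissing = 0L,
                           nRetained = 0L, projectionTarget = m)))
  }
  keep <- biallelic

  nExcludedBed <- 0L
  if (!is.null(excludeBed)) {
    pos <- as.numeric(fix[, "POS"]); chrom <- fix[, "CHROM"]
    inBed <- rep(FALSE, nrow(fix))
    for (i in seq_len(nrow(excludeBed))) {
      inBed <- inBed | (chrom == excludeBed$chrom[i] &
                        pos - 1 >= excludeBed$start[i] &
                        pos - 1 < excludeBed$end[i])
    }
    nExcludedBed <- sum(keep & inBed)
    keep <- keep & !inBed
  }

  idx <- which(keep)
  nsamp <- ncol(gt)
  altCount <- integer(length(idx)); called <- integer(length(idx))
  okSite <- logical(length(idx))
  ploidySeen <- NA_integer_
  for (ii in seq_along(idx)) {
    alle <- lapply(gt[idx[ii], ], .gtAlleles)
    known <- !vapply(alle, is.null, logical(1))
    pl <- unique(vapply(alle[known], length, integer(1)))
    if (length(pl) > 1L)
      stop("mixed-ploidy genotypes at a site: X dosage cannot be counted; ",
           "supply single-sex samples")
    if (length(pl) == 1L) {
      if (is.na(ploidySeen)) ploidySeen <- pl
      else if (ploidySeen != pl)
        stop("ploidy differs between sites; mixed X dosage is not supported")
    }
    av <- unlist(alle[known])
    nMissGeno <- sum(!known) +
      sum(vapply(alle[known], function(a) any(is.na(a)), logical(1)))
    okSite[ii] <- nMissGeno / nsamp <= maxMissing
    altCount[ii] <- sum(av == 1L, na.rm = TRUE)
    called[ii] <- sum(!is.na(av))
  }
  nFilteredMissing <- sum(!okSite)
  altCount <- altCount[okSite]; called <- called[okSite]
  if (!length(altCount))
    stop("no sites survive the filters")

  m <- if (is.null(project)) min(called) else as.integer(project)
  if (any(called < m))
    stop("projection target exceeds the called chromosomes at some sites")
  ## hypergeometric projection of each site to m chromosomes
  sfs <- numeric(m - 1L)
  preMass <- sum(altCount > 0 & altCount < called)
  for (ii in seq_along(altCount)) {
    j <- altCount[ii]; c0 <- called[ii]
    if (j == 0L || j == c0) next  # monomorphic in the sample
    jj <- 1:(m - 1L)
    w <- exp(lchoose(j, jj) + lchoose(c0 - j, m - jj) - lchoose(c0, m))
    w[!is.finite(w)] <- 0
    sfs <- sfs + w
  }
  postMass <- sum(sfs)
  nRetained <- length(altCount)

  out <- spectrumData(sfs, n = m, folded = FALSE, L = rawLength, mu = mu,
                      chromClass = chromClass)
  if (fold) out <- foldSFS(out)
  retained <- (nRetained / nBiallelic) *
    (if (preMass > 0) postMass / preMass else 1)
  adj <- rawLength * retained
  out@L <- adj
  list(sfs = out,
       callable = list(raw = rawLength, retainedFraction = retained,
                       adjusted = adj),
       log = list(nSitesTotal = nSitesTotal, nBiallelic = nBiallelic,
                  nExcludedBed = nExcludedBed,
                  nFilteredMissing = nFilteredMissing,
                  nRetained = nRetained, projectionTarget = m))
}
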