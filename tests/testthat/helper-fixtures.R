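# Shared fixtures and independent brute-force oracles used across tests.

# Write a small VCF with the given genotype rows (list of character vectors,
# one per site) and fixed columns.
writeTestVCF <- function(rows, path = tempfile(fileext = ".vcf"),
                         samples = paste0("S", seq_along(rows[[1]]$gt))) {
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r)
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT",
            r$gt), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

# Brute-force SFS from an explicit genotype matrix (rows = sites, entries =
# alt-allele dosage per chromosome column), no missingness.
bruteSFSFromMatrix <- function(alleleMat) {
  n <- ncol(alleleMat)
  counts <- numeric(n - 1)
  for (i in seq_len(nrow(alleleMat))) {
    j <- sum(alleleMat[i, ])
    if (j >= 1 && j <= n - 1) counts[j] <- counts[j] + 1
  }
  counts
}

# Brute-force average pairwise difference per site from a haplotype matrix
# (rows = haplotypes, columns = sites with 0/1 alleles).
brutePi <- function(hap, L) {
  n <- nrow(hap)
  tot <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    tot <- tot + sum(hap[a, ] != hap[b, ])
  tot / choose(n, 2) / L
}

# Expand an SFS into one explicit haplotype matrix realizing it.
hapFromSFS <- function(counts, n) {
  nSites <- sum(counts)
  hap <- matrix(0L, nrow = n, ncol = max(nSites, 1))
  col <- 0L
  for (i in seq_along(counts)) {
    for (s in seq_len(counts[i])) {
      col <- col + 1L
      hap[sample.int(n, i), col] <- 1L
    }
  }
  hap[, seq_len(max(col, 1)), drop = FALSE]
}

# Brute-force hypergeometric projection by enumerating subsets is
# equivalent to the expectation over draws; here computed by direct
# simulation of subsampling without replacement.
bruteProject <- function(counts, n, m, reps = 20000) {
  out <- numeric(m - 1)
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    for (r in seq_len(reps)) {
      j <- sum(sample(c(rep(1L, i), rep(0L, n - i)), m))
      if (j >= 1 && j <= m - 1) out[j] <- out[j] + counts[i] / reps
    }
  }
  out
}

# The study's bottleneck truth on the coalescent-unit scale (for warm
# starts in slow tests).
bottleneckTruth <- function() {
  c(nuB = 1861 / 14500, nuF = 1e5 / 14500,
    dB = 1120 / 29000, dF = 920 / 29000)
}
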