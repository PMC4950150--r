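#' Simulate genotypes for a family-structured population
#'
#' Emulates a wild-population genotyping panel with a mix of close relatives
#' and unrelated individuals. Per SNP an allele frequency p is drawn from
#' Uniform(mafLow, mafHigh); unrelated individuals and (ungenotyped) founder
#' parents are drawn from Hardy-Weinberg proportions; each family contributes
#' \code{sibsPerFamily} full sibs by Mendelian transmission from its two
#' founder parents. Full-sib pairs therefore have genomic relationships
#' centered near 0.5.
#'
#' @param nFamilies number of full-sib families.
#' @param sibsPerFamily genotyped sibs per family.
#' @param nUnrelated additional unrelated individuals.
#' @param nSnps number of SNPs.
#' @param mafLow,mafHigh allele-frequency bounds, in (0, 0.5].
#' @param missingRate fraction of calls set missing at random (default 0).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return a \linkS4class{GenotypeMatrix} with
#'   \code{nFamilies * sibsPerFamily + nUnrelated} individuals.
#' @examples
#' gm <- simulateGenotypes(nFamilies = 10, sibsPerFamily = 2, nUnrelated = 20,
#'                         nSnps = 500, seed = 42)
#' gm
#' @export
simulateGenotypes <- function(nFamilies, sibsPerFamily = 2, nUnrelated = 0,
                              nSnps = 1000, mafLow = 0.01, mafHigh = 0.5,
                              missingRate = 0, seed = NULL) {
  stopifnot(mafLow > 0, mafHigh <= 0.5, mafLow <= mafHigh,
            nFamilies >= 0, sibsPerFamily >= 1, nUnrelated >= 0, nSnps >= 1)
  n <- nFamilies * sibsPerFamily + nUnrelated
  if (n < 1) stop("no individuals requested")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(nSnps, mafLow, mafHigh)

  draw_founder <- function(k) {
    # k x nSnps HWE dosages
    matrix(stats::rbinom(k * nSnps, 2, rep(p, each = k)), nrow = k)
  }
  transmit <- function(parents, k) {
    # k offspring gametes from each of k parent rows (dosage/2 = allele prob)
    matrix(stats::rbinom(k * nSnps, 1, parents / 2), nrow = k)
  }

  rows <- vector("list", 2)
  ids <- character(0)
  dos <- matrix(0, nrow = n, ncol = nSnps)
  r <- 0L
  if (nFamilies > 0) {
    for (fam in seq_len(nFamilies)) {
      dam <- draw_founder(1)
      sire <- draw_founder(1)
      for (s in seq_len(sibsPerFamily)) {
        kid <- transmit(dam, 1) + transmit(sire, 1)
        r <- r + 1L
        dos[r, ] <- kid
        ids <- c(ids, sprintf("fam%03d_sib%d", fam, s))
      }
    }
  }
  if (nUnrelated > 0) {
    dos[(r + 1L):n, ] <- draw_founder(nUnrelated)
    ids <- c(ids, sprintf("unrel%04d", seq_len(nUnrelated)))
  }
  if (missingRate > 0) {
    miss <- stats::runif(length(dos)) < missingRate
    dos[miss] <- NA
  }
  dimnames(dos) <- list(ids, sprintf("snp%05d", seq_len(nSnps)))
  GenotypeMatrix(dos, snpInfo = data.frame(id = colnames(dos),
    chrom = as.character(1 + (seq_len(nSnps) - 1) %% 24),
    pos = as.integer(seq_len(nSnps) * 1000L),
    ref = "A", alt = "B"))
}
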