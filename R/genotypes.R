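#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix (individuals x SNPs) with entries 0/1/2/NA;
#'   rownames are individual ids. Column names are used as SNP ids when
#'   \code{snpInfo} is not supplied.
#' @param snpInfo optional per-SNP metadata (data.frame or DataFrame with
#'   columns id, chrom, pos, ref, alt); defaults are filled in.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0, 2, 1, 1), 2, 2,
#'   dimnames = list(c("a", "b"), c("s1", "s2"))))
#' alleleFreq(gm)
#' @export
GenotypeMatrix <- function(dosages, snpInfo = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  if (is.null(snpInfo)) {
    snpInfo <- S4Vectors::DataFrame(id = colnames(dosages),
      chrom = NA_character_, pos = NA_integer_,
      ref = NA_character_, alt = NA_character_)
  } else {
    snpInfo <- S4Vectors::DataFrame(snpInfo)
    for (col in c("chrom", "ref", "alt"))
      if (!col %in% colnames(snpInfo)) snpInfo[[col]] <- NA_character_
    if (!"pos" %in% colnames(snpInfo)) snpInfo$pos <- NA_integer_
    if (!"id" %in% colnames(snpInfo)) snpInfo$id <- colnames(dosages)
  }
  snpInfo <- snpInfo[, c("id", "chrom", "pos", "ref", "alt")]
  colnames(dosages) <- snpInfo$id
  new("GenotypeMatrix", dosages = dosages, snpInfo = snpInfo)
}

#' Subset a GenotypeMatrix
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param i individual (row) index; @param j SNP (column) index.
#' @param ...,drop ignored (subsetting never drops to a vector).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  new("GenotypeMatrix", dosages = x@dosages[i, j, drop = FALSE],
      snpInfo = x@snpInfo[j, , drop = FALSE])
})

#' Read genotypes from a VCF file
#'
#' Converts GT fields of a (plain or bgzipped) VCF into allele dosages
#' counting ALT alleles. Multi-allelic sites are skipped with a warning; the
#' dosage model is bi-allelic. Missing genotypes (\code{./.} or \code{.})
#' become \code{NA}. Site order is preserved.
#'
#' @param path path to the VCF file.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readVCF <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("empty genotype set: no usable sites in ", path)
  multi <- grepl(",", fix$ALT %||% "") | is.na(fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("empty genotype set: no bi-allelic sites in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count ALT alleles in GT strings like 0/1, 1|1, ./.
  count_alt <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(al) {
      if (any(al == "." | is.na(al))) return(NA_real_)
      sum(al == "1")
    }, numeric(1))
  }
  gt[is.na(gt)] <- "."
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(rownames(gt), names(dos)))
  dos <- t(dos)  # individuals x SNPs
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  colnames(dos) <- ids
  GenotypeMatrix(dos, snpInfo = data.frame(id = ids, chrom = fix$CHROM,
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a plain dosage table
#'
#' Tab-separated, first column the individual id, header row of SNP ids,
#' entries 0/1/2 or the missing code.
#'
#' @param path file path.
#' @param missing string coding a missing dosage (default \code{"NA"}).
#' @return \code{readDosageTable}: a \linkS4class{GenotypeMatrix}.
#' @export
readDosageTable <- function(path, missing = "NA") {
  if (!file.exists(path)) stop("cannot read dosage table: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE,
    na.strings = character(0))
  if (ncol(tab) < 2L) stop("dosage table needs an id column plus SNP columns")
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- matrix(!(vals %in% c("0", "1", "2", missing)), nrow(vals))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage '%s' at row %d (individual %s), column %s",
      vals[bad][1L], w[1L], ids[w[1L]], colnames(vals)[w[2L]]))
  }
  vals[vals == missing] <- NA
  dos <- matrix(as.numeric(vals), nrow = nrow(vals),
    dimnames = list(ids, colnames(vals)))
  GenotypeMatrix(dos)
}

#' @rdname readDosageTable
#' @param gm a \linkS4class{GenotypeMatrix} to write.
#' @return \code{writeDosageTable}: the path, invisibly.
#' @export
writeDosageTable <- function(gm, path, missing = "NA") {
  d <- dosages(gm)
  out <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
    na = missing)
  invisible(path)
}

#' Per-SNP allele frequency, MAF and call rate
#'
#' \code{alleleFreq} returns the frequency of the non-reference allele,
#' \code{sum(dosage) / (2 * n_nonmissing)}; \code{minorAlleleFreq} folds it to
#' \code{min(f, 1 - f)}; \code{callRate} is the fraction of non-missing calls.
#' SNPs with no non-missing call get \code{NaN} frequency (they are removed by
#' the call-rate filter).
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return named numeric vector, one entry per SNP.
#' @export
alleleFreq <- function(gm) {
  d <- dosages(gm)
  nn <- colSums(!is.na(d))
  colSums(d, na.rm = TRUE) / (2 * nn)
}

#' @rdname alleleFreq
#' @export
minorAlleleFreq <- function(gm) {
  f <- alleleFreq(gm)
  pmin(f, 1 - f)
}

#' @rdname alleleFreq
#' @export
callRate <- function(gm) {
  d <- dosages(gm)
  colMeans(!is.na(d))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts against
#' Hardy-Weinberg expectations computed from the observed allele frequency.
#' Monomorphic sites (one allele absent) return p = 1 by convention.
#'
#' @param nAA,nAa,naa non-negative genotype counts (reference homozygote,
#'   heterozygote, alternative homozygote). Vectorized.
#' @return p-value(s).
#' @examples
#' hweTest(25, 50, 25)  # perfect HWE -> 1
#' hweTest(50, 0, 50)   # maximal disequilibrium
#' @export
hweTest <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (any(n <= 0)) stop("total genotype count must be positive")
  p <- (2 * naa + nAa) / (2 * n)  # alt-allele frequency
  q <- 1 - p
  exp_counts <- cbind(n * q^2, 2 * n * p * q, n * p^2)
  obs <- cbind(nAA, nAa, naa)
  stat <- numeric(length(n))
  for (k in 1:3) {
    e <- exp_counts[, k]
    contrib <- ifelse(e > 0, (obs[, k] - e)^2 / e, 0)
    stat <- stat + contrib
  }
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pval[p == 0 | p == 1] <- 1  # monomorphic
  unname(pval)
}

hweTestGm <- function(gm) {
  d <- dosages(gm)
  nAA <- colSums(d == 0, na.rm = TRUE)
  nAa <- colSums(d == 1, na.rm = TRUE)
  naa <- colSums(d == 2, na.rm = TRUE)
  tot <- nAA + nAa + naa
  p <- rep(1, ncol(d))
  ok <- tot > 0
  p[ok] <- hweTest(nAA[ok], nAa[ok], naa[ok])
  p
}

#' SNP quality-control filter
#'
#' Retains SNPs with call rate >= \code{minCallRate}, minor allele frequency
#' >= \code{minMaf} and Hardy-Weinberg p-value > \code{minHweP} (defaults:
#' 0.95, 0.01, 0.001). A SNP failing several rules is counted under each in
#' the report.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param minCallRate,minMaf,minHweP thresholds.
#' @return list with elements \code{genotypes} (filtered
#'   \linkS4class{GenotypeMatrix}) and \code{report} (\linkS4class{QCReport}).
#' @export
qcFilter <- function(gm, minCallRate = 0.95, minMaf = 0.01, minHweP = 0.001) {
  cr <- callRate(gm)
  maf <- minorAlleleFreq(gm)
  maf[is.nan(maf)] <- 0
  hwe <- hweTestGm(gm)
  failCr <- cr < minCallRate
  failMaf <- maf < minMaf
  failHwe <- hwe <= minHweP
  keep <- !(failCr | failMaf | failHwe)
  if (!any(keep)) stop("QC removed all SNPs")
  rep <- new("QCReport", nInput = ncol(dosages(gm)), nPassed = sum(keep),
    nFailedCallRate = sum(failCr), nFailedMaf = sum(failMaf),
    nFailedHwe = sum(failHwe),
    thresholds = c(minCallRate = minCallRate, minMaf = minMaf,
                   minHweP = minHweP))
  list(genotypes = gm[, keep], report = rep)
}
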