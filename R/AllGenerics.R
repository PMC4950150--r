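#' Accessors for rmgwas classes
#'
#' Small accessor generics: \code{dosages}, \code{individualIds},
#' \code{snpInfo}, \code{nIndividuals}, \code{nSnps} for
#' \linkS4class{GenotypeMatrix}; \code{grmValues} for
#' \linkS4class{RelationshipMatrix}; \code{varComp}, \code{fixef},
#' \code{logLikREML} for \linkS4class{NullFit}; \code{scanTable} and
#' \code{lambdaGC} for \linkS4class{RglsScan}.
#'
#' @param x an object of the documented class.
#' @return the slot contents (matrix, DataFrame, numeric vector or scalar).
#' @name accessors
#' @aliases dosages individualIds snpInfo nIndividuals nSnps grmValues
#'   varComp fixef logLikREML scanTable lambdaGC
#' @examples
#' gm <- simulateGenotypes(nFamilies = 2, sibsPerFamily = 2, nUnrelated = 2,
#'                         nSnps = 5, seed = 1)
#' dim(dosages(gm)); nSnps(gm); individualIds(gm)
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))
#' @rdname accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname accessors
#' @export
setGeneric("fixef", function(x) standardGeneric("fixef"))
#' @rdname accessors
#' @export
setGeneric("logLikREML", function(x) standardGeneric("logLikREML"))
#' @rdname accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))
#' @rdname accessors
#' @export
setGeneric("lambdaGC", function(x) standardGeneric("lambdaGC"))

#' Apply a whitening rotation
#'
#' Applies the factorized V0^{-1/2} operator to an observation-level vector or
#' matrix (one row per observation).
#'
#' @param object a \linkS4class{RotationOperator}.
#' @param v numeric vector of length N or matrix with N rows.
#' @return the rotated vector/matrix, same shape as \code{v}.
#' @seealso [makeRotation()]
#' @export
setGeneric("rotate", function(object, v) standardGeneric("rotate"))

setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@dosages))
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@dosages))
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosages))

setMethod("grmValues", "RelationshipMatrix", function(x) x@values)
setMethod("individualIds", "RelationshipMatrix", function(x) rownames(x@values))
setMethod("nIndividuals", "RelationshipMatrix", function(x) nrow(x@values))

setMethod("varComp", "NullFit", function(x) x@components)
setMethod("fixef", "NullFit", function(x) x@betaFixed)
setMethod("logLikREML", "NullFit", function(x) x@loglikREML)

setMethod("scanTable", "RglsScan", function(x) x@table)
setMethod("lambdaGC", "RglsScan", function(x) x@lambdaGC)
setMethod("varComp", "RglsScan", function(x) x@components)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "individuals x", ncol(d), "SNPs\n")
  miss <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  mafs <- minorAlleleFreq(object)
  if (length(mafs))
    cat(sprintf("  MAF range: %.3f - %.3f\n",
                suppressWarnings(min(mafs, na.rm = TRUE)),
                suppressWarnings(max(mafs, na.rm = TRUE))))
})

setMethod("show", "RelationshipMatrix", function(object) {
  v <- object@values
  cat("RelationshipMatrix (VanRaden G):", nrow(v), "individuals\n")
  cat(sprintf("  mean diagonal: %.3f; max off-diagonal: %.3f\n",
              mean(diag(v)), max(v - diag(diag(v)))))
})

setMethod("show", "QCReport", function(object) {
  cat("SNP QC report\n")
  cat("  input SNPs:      ", object@nInput, "\n")
  cat("  passed:          ", object@nPassed, "\n")
  cat("  failed call rate:", object@nFailedCallRate,
      sprintf("(< %.3g)\n", object@thresholds["minCallRate"]))
  cat("  failed MAF:      ", object@nFailedMaf,
      sprintf("(< %.3g)\n", object@thresholds["minMaf"]))
  cat("  failed HWE:      ", object@nFailedHwe,
      sprintf("(p <= %.3g)\n", object@thresholds["minHweP"]))
})

setMethod("show", "NullFit", function(object) {
  vc <- object@components
  cat("Repeated-measures null model (REML)\n")
  cat(sprintf("  individuals: %d   observations: %d\n",
              length(object@counts), length(object@y)))
  cat(sprintf("  sigma_g2 = %.4g  sigma_p2 = %.4g  sigma_e2 = %.4g\n",
              vc["sigma_g2"], vc["sigma_p2"], vc["sigma_e2"]))
  if (any(object@boundary))
    cat("  note: component(s) at lower boundary:",
        paste(names(vc)[object@boundary], collapse = ", "), "\n")
  cat(sprintf("  REML log-likelihood: %.4f\n", object@loglikREML))
})

setMethod("show", "RglsScan", function(object) {
  tab <- object@table
  cat("Rotated-GLS association scan:", nrow(tab), "SNPs\n")
  cat(sprintf("  lambda (genomic control): %.3f\n", object@lambdaGC))
  ok <- !tab$excluded
  if (any(ok)) {
    top <- which.min(ifelse(ok, tab$p, Inf))
    cat(sprintf("  top SNP: %s  beta = %.3f  p = %.3g\n",
                tab$snp_id[top], tab$beta[top], tab$p[top]))
  }
})
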