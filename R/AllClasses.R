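#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' GenotypeMatrix: individuals-by-SNPs dosage matrix
#'
#' Stores SNP genotypes as allele dosages (0, 1 or 2 copies of the
#' non-reference allele; \code{NA} for missing calls) for a set of uniquely
#' labelled individuals, together with per-SNP metadata (id, chromosome,
#' position, ref/alt alleles). Rows are individuals, columns SNPs.
#'
#' @slot dosages numeric matrix, n individuals x m SNPs, entries in
#'   \{0, 1, 2, NA\}; dimnames carry individual ids and SNP ids.
#' @slot snpInfo a \link[S4Vectors]{DataFrame} with one row per SNP and
#'   columns \code{id}, \code{chrom}, \code{pos}, \code{ref}, \code{alt}.
#'
#' @seealso [GenotypeMatrix()], [dosages()], [qcFilter()], [computeGRM()]
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snpInfo = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  msg <- character(0)
  ids <- rownames(d)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "individual ids (rownames) must be present and unique")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
  if (nrow(object@snpInfo) != ncol(d))
    msg <- c(msg, "snpInfo must have one row per SNP column")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(object@snpInfo)))
    msg <- c(msg, paste("snpInfo must have columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' RelationshipMatrix: genomic relationship matrix
#'
#' Symmetric n x n matrix of realized genomic relationships between
#' individuals (VanRaden method 1). An internal cache environment memoizes the
#' eigendecomposition, which is reused by the null-model fit, the scan
#' whitening and multivariate-normal sampling of polygenic effects.
#'
#' @slot values symmetric numeric matrix with individual ids as dimnames.
#' @slot cache environment used to memoize the eigendecomposition.
#' @seealso [computeGRM()], [grmValues()], [grmEigen()]
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", cache = "environment"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "matrix must be symmetric (1e-10)")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "individual ids (dimnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' QCReport: summary of SNP quality-control filtering
#'
#' @slot nInput,nPassed number of SNPs before/after filtering.
#' @slot nFailedCallRate,nFailedMaf,nFailedHwe per-rule failure counts; a SNP
#'   failing several rules is counted under each.
#' @slot thresholds named numeric vector (minCallRate, minMaf, minHweP).
#' @seealso [qcFilter()]
#' @export
setClass("QCReport",
  representation(nInput = "integer", nPassed = "integer",
    nFailedCallRate = "integer", nFailedMaf = "integer",
    nFailedHwe = "integer", thresholds = "numeric"))

#' NullFit: fitted SNP-free repeated-measures mixed model
#'
#' Result of fitting y = X beta + Z g + Z p + e by REML, where g is the
#' polygenic effect (covariance sigma_g^2 G), p the permanent-environment
#' effect (sigma_p^2 I_n) and e the residual (sigma_e^2 I_N). The phenotypic
#' covariance V0 = Z G Z' sigma_g^2 + Z Z' sigma_p^2 + I sigma_e^2 is stored
#' in factorized form: V0 = B Q S Q' B' + sigma_e^2 (I - B B') + sigma_e^2 B B'
#' with B = Z D^{-1/2} (D = diag of per-individual record counts) an
#' orthonormal basis, so eigenvalues are S + sigma_e^2 on the n individual
#' directions and sigma_e^2 on the N - n complement.
#'
#' @slot components named numeric: sigma_g2, sigma_p2, sigma_e2.
#' @slot boundary logical flags marking components floored at the lower bound.
#' @slot betaFixed named numeric vector of GLS fixed-effect estimates.
#' @slot loglikREML restricted log-likelihood at the optimum (up to constant).
#' @slot zIndex integer N-vector mapping each observation to its individual.
#' @slot counts integer n-vector of records per individual (diagonal of Z'Z).
#' @slot Q,S eigenvectors/eigenvalues of D^{1/2} A D^{1/2},
#'   A = sigma_g2 G + sigma_p2 I.
#' @slot X fixed-effect design matrix (N x p); @slot y response (length N).
#' @slot individualIds labels, ordered as in the GRM.
#' @seealso [fitNull()], [varComp()], [nullCovariance()], [makeRotation()]
#' @export
setClass("NullFit",
  representation(components = "numeric", boundary = "logical",
    betaFixed = "numeric", loglikREML = "numeric",
    zIndex = "integer", counts = "integer",
    Q = "matrix", S = "numeric",
    X = "matrix", y = "numeric", individualIds = "character"))

#' RotationOperator: whitening transform for the fitted covariance
#'
#' Applies V0^{-1/2} (the symmetric inverse square root of the null-model
#' covariance) to observation-level vectors or matrices, turning the
#' generalized least-squares SNP fit into ordinary least squares with
#' independent homoscedastic residuals. Held in factorized low-rank form;
#' the implicit eigenvalues of V0 are \code{lambdaTop} (n values) plus
#' \code{sigmaE2} with multiplicity N - n.
#'
#' @slot zIndex,counts observation-to-individual map and per-individual counts.
#' @slot Q n x n orthonormal matrix (individual-space eigenvectors).
#' @slot lambdaTop eigenvalues of V0 on the individual-space directions.
#' @slot sigmaE2 residual variance = eigenvalue on the complement space.
#' @seealso [makeRotation()], [rotate()]
#' @export
setClass("RotationOperator",
  representation(zIndex = "integer", counts = "integer", Q = "matrix",
    lambdaTop = "numeric", sigmaE2 = "numeric"))

#' RglsScan: per-SNP association results
#'
#' One row per SNP with the rotated-GLS effect estimate, standard error,
#' Wald statistic, p-value, sample size and minor allele frequency, plus the
#' scan-level genomic-control inflation factor and the variance components of
#' the null model used for whitening.
#'
#' @slot table a \link[S4Vectors]{DataFrame} with columns snp_id, chrom, pos,
#'   maf, n, beta, se, z, p, excluded.
#' @slot lambdaGC median-based genomic-control inflation factor.
#' @slot components variance components of the null fit.
#' @seealso [rglsScan()], [scanTable()], [inflationLambda()]
#' @export
setClass("RglsScan",
  representation(table = "DataFrame", lambdaGC = "numeric",
    components = "numeric"))

#' SimTruth: realized values behind a simulated phenotype set
#'
#' Retains everything needed for recovery tests: the drawn polygenic and
#' permanent-environment effects, year effects, underlying liabilities and
#' threshold (binary traits), QTL positions/effects and variance components.
#'
#' @slot g,p named per-individual polygenic / permanent-environment draws.
#' @slot yearEffects named per-year draws (empty if no year effects).
#' @slot liability observation-level underlying Gaussian trait.
#' @slot tau threshold on the liability scale (NA for Gaussian traits).
#' @slot qtlIndices,qtlEffects QTL positions among SNP columns and effects.
#' @slot components named sigma_g2/sigma_p2/sigma_e2 used; @slot seed the seed.
#' @seealso [simulateGaussian()], [simulateBinary()]
#' @export
setClass("SimTruth",
  representation(g = "numeric", p = "numeric", yearEffects = "numeric",
    liability = "numeric", tau = "numeric",
    qtlIndices = "integer", qtlEffects = "numeric",
    components = "numeric", seed = "integerOrNULL"))
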