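#' Whitening operator from a fitted null model
#'
#' Builds the operator that multiplies observation-level data by V0^{-1/2}
#' (symmetric inverse square root of the fitted covariance), producing an
#' equivalent linear model with independent, homoscedastic residuals so each
#' SNP can be fitted by ordinary least squares. The eigendecomposition behind
#' it is computed once per trait from the low-rank structure
#' V0 = Z A Z' + sigma_e2 I (n non-trivial eigenvalues; the remaining N - n
#' equal sigma_e2), never as a dense N x N factorization.
#'
#' @param fit a \linkS4class{NullFit}.
#' @return a \linkS4class{RotationOperator}.
#' @export
makeRotation <- function(fit) {
  se2 <- fit@components["sigma_e2"]
  lambdaTop <- fit@S + se2
  floorv <- 1e-8 * max(lambdaTop)
  if (any(lambdaTop < floorv)) lambdaTop <- pmax(lambdaTop, floorv)
  if (any(lambdaTop <= 0) || se2 <= 0)
    stop("non-positive eigenvalue in fitted covariance")
  new("RotationOperator", zIndex = fit@zIndex, counts = fit@counts,
    Q = fit@Q, lambdaTop = as.numeric(lambdaTop),
    sigmaE2 = as.numeric(se2))
}

#' @describeIn makeRotation apply the operator: for a vector or matrix
#'   \code{v} (N rows), returns V0^{-1/2} v.
#' @param object a \linkS4class{RotationOperator}; @param v vector or matrix.
#' @export
setMethod("rotate", "RotationOperator", function(object, v) {
  vec <- is.null(dim(v))
  V <- if (vec) matrix(v, ncol = 1) else as.matrix(v)
  se <- sqrt(object@sigmaE2)
  dh <- sqrt(object@counts)
  shrink <- 1 - se / sqrt(object@lambdaTop)
  Bt <- rowsum(V, object@zIndex) / dh          # B'v, n x k
  t1 <- crossprod(object@Q, Bt)
  t2 <- object@Q %*% (shrink * t1)
  expand <- (t2 / dh)[object@zIndex, , drop = FALSE]
  out <- (V - expand) / se
  if (vec) out[, 1] else out
})

#' Two-sided Wald p-value from a standard-normal statistic
#'
#' @param statistic finite z statistic(s).
#' @return two-sided standard-normal tail probability, in (0, 1].
#' @examples
#' waldP(0)          # 1
#' waldP(1.959964)   # 0.05
#' @export
waldP <- function(statistic) {
  # clamped below so extreme statistics keep p in (0, 1]
  pmax(2 * stats::pnorm(-abs(statistic)), .Machine$double.xmin)
}

#' Genomic-control inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and compares their median
#' to the null median 0.4549364 (\code{method = "median"}, the default) or
#' regresses observed on expected quantiles through the origin
#' (\code{method = "regression"}).
#'
#' @param p vector of p-values (at least 10 finite values).
#' @param method "median" or "regression".
#' @return the scalar inflation factor lambda.
#' @export
inflationLambda <- function(p, method = c("median", "regression")) {
  method <- match.arg(method)
  p <- p[is.finite(p)]
  if (length(p) < 10L)
    stop("need at least 10 finite p-values to estimate lambda")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  if (method == "median") {
    stats::median(chi) / stats::qchisq(0.5, df = 1)
  } else {
    m <- length(chi)
    expd <- stats::qchisq(stats::ppoints(m), df = 1)
    obs <- sort(chi)
    sum(expd * obs) / sum(expd^2)
  }
}

#' Rotated generalized least-squares association scan
#'
#' Stage 2 of the two-stage method: every SNP is fitted in the generalized
#' least-squares model y = X beta + x_snp beta_snp + e, e ~ N(0, V0), with V0
#' fixed at the null-model estimate. After whitening by [makeRotation()] this
#' is ordinary least squares; the QR factorization of the whitened fixed
#' design is computed once and each SNP is tested on its residualized
#' (Frisch-Waugh) dosage column. The Wald statistic uses the per-SNP residual
#' variance RSS / (N - rank), referred to the standard normal. Missing
#' dosages are mean-imputed per SNP; SNPs with zero dosage variance are
#' flagged, excluded from the inflation factor, and carry NA results.
#'
#' @param gm a \linkS4class{GenotypeMatrix} covering every phenotyped
#'   individual of the null fit.
#' @param fit the \linkS4class{NullFit} for the same phenotype records (its
#'   fixed-effect design is carried unchanged into the scan).
#' @param lambdaMethod method passed to [inflationLambda()].
#' @return an \linkS4class{RglsScan}.
#' @examples
#' gm <- simulateGenotypes(nFamilies = 20, sibsPerFamily = 2, nUnrelated = 20,
#'                         nSnps = 200, seed = 11)
#' G <- computeGRM(gm)
#' sim <- simulateGaussian(gm, qtlIndices = 7, qtlEffects = 1,
#'                         components = c(1, 1, 1),
#'                         design = designSpec("balanced", 4), seed = 11,
#'                         grm = G)
#' fit <- fitNull(sim$pheno, ~ 1, G)
#' rglsScan(gm, fit)
#' @export
rglsScan <- function(gm, fit, lambdaMethod = "median") {
  ids <- fit@individualIds
  map <- match(ids, individualIds(gm))
  if (anyNA(map))
    stop("phenotyped ids missing from genotypes: ",
         paste(utils::head(ids[is.na(map)], 5), collapse = ", "))
  D <- dosages(gm)[map, , drop = FALSE]
  m <- ncol(D)
  nUsed <- colSums(!is.na(D))
  freq <- colSums(D, na.rm = TRUE) / (2 * pmax(nUsed, 1))
  # mean imputation (2p) per SNP
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- 2 * freq[idx[, 2]]
  }

  # Whitened cross-products without expanding SNPs to observation level:
  # for observation-level vectors u, v,
  #   u' V0^{-1} v = (1/se2) [u'v - sum(w * (Q'B'u)(Q'B'v))],
  # w = S / (S + se2), and a SNP column is x = (Z M)_j, so Z'x = D M_j and
  # B'x = D^{1/2} M_j: everything reduces to individual-level algebra. The
  # per-SNP OLS-on-rotated-data fit (QR of the whitened fixed block, then
  # the residualized SNP regression) is evaluated through these products.
  y <- fit@y
  X <- fit@X
  N <- length(y)
  pDim <- ncol(X)
  zi <- fit@zIndex
  cnt <- fit@counts
  dh <- sqrt(cnt)
  se2 <- fit@components["sigma_e2"]
  w <- fit@S / (fit@S + se2)

  Zty <- rowsum(y, zi)[, 1]
  ZtX <- rowsum(X, zi)
  uy <- crossprod(fit@Q, Zty / dh)[, 1]
  UX <- crossprod(fit@Q, ZtX / dh)
  U <- crossprod(fit@Q, dh * D)

  yVy <- (sum(y^2) - sum(w * uy^2)) / se2
  C <- (crossprod(X) - crossprod(UX, w * UX)) / se2
  dvec <- (crossprod(X, y)[, 1] - crossprod(UX, w * uy)[, 1]) / se2
  aSnp <- (colSums(cnt * D^2) - colSums(w * U^2)) / se2
  bSnp <- (crossprod(D, Zty)[, 1] - crossprod(U, w * uy)[, 1]) / se2
  Cc <- (t(crossprod(D, ZtX)) - crossprod(UX, w * U)) / se2  # p x m

  cC <- chol((C + t(C)) / 2)
  h <- backsolve(cC, forwardsolve(t(cC), dvec))
  Ei <- backsolve(cC, forwardsolve(t(cC), Cc))
  sxx <- aSnp - colSums(Cc * Ei)
  sxy <- bSnp - colSums(Cc * h)
  rss0 <- yVy - sum(dvec * h)

  cm <- colMeans(D)
  varD <- (colSums(D^2) - nrow(D) * cm^2) / max(nrow(D) - 1, 1)
  excluded <- varD < 1e-12 | sxx < 1e-10
  sxx[excluded] <- NA_real_  # keeps the sqrt below quiet for flagged SNPs
  df <- N - pDim - 1L
  beta <- sxy / sxx
  rss <- pmax(rss0 - beta * sxy, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  z <- beta / se
  p <- waldP(z)
  beta[excluded] <- se[excluded] <- z[excluded] <- p[excluded] <- NA_real_

  info <- snpInfo(gm)
  tab <- S4Vectors::DataFrame(snp_id = info$id, chrom = info$chrom,
    pos = info$pos, maf = unname(pmin(freq, 1 - freq)), n = unname(nUsed),
    beta = unname(beta), se = unname(se), z = unname(z), p = unname(p),
    excluded = unname(excluded))
  lam <- if (sum(!excluded) >= 10L)
    inflationLambda(p[!excluded], method = lambdaMethod) else NA_real_
  new("RglsScan", table = tab, lambdaGC = lam, components = fit@components)
}

#' Genome-wide significant SNPs after multiplicity adjustment
#'
#' Convenience filter: adjusts scan p-values (default Bonferroni) and returns
#' the rows passing \code{alpha}. The scan itself reports raw p-values.
#'
#' @param scan an \linkS4class{RglsScan}.
#' @param alpha family-wise (or FDR) level.
#' @param method any method accepted by [stats::p.adjust()].
#' @return a DataFrame of significant rows with an \code{p_adj} column.
#' @export
significantSnps <- function(scan, alpha = 0.05, method = "bonferroni") {
  tab <- scanTable(scan)
  ok <- !tab$excluded
  padj <- rep(NA_real_, nrow(tab))
  padj[ok] <- stats::p.adjust(tab$p[ok], method = method)
  tab$p_adj <- padj
  tab[ok & padj <= alpha, ]
}

#' Write scan results as TSV
#'
#' Columns snp_id, chrom, pos, maf, n, beta, se, z, p; a leading comment line
#' records the variance components and the inflation factor.
#'
#' @param scan an \linkS4class{RglsScan}; @param path output path.
#' @return the path, invisibly.
#' @export
writeScanTable <- function(scan, path) {
  vc <- varComp(scan)
  hdr <- sprintf("# sigma_g2=%.6g sigma_p2=%.6g sigma_e2=%.6g lambda=%.4f",
    vc["sigma_g2"], vc["sigma_p2"], vc["sigma_e2"], lambdaGC(scan))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- as.data.frame(scanTable(scan))
  tab$excluded <- NULL
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
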