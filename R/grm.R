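#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = W W' / (2 * sum_k p_k (1 - p_k)), where W is the dosage matrix with
#' column k centered by 2 p_k and p_k the sample frequency of the
#' non-reference allele. Missing dosages are mean-imputed (2 p_k) before
#' centering, so they contribute zero. For an outbred sample the diagonal
#' averages near 1; full sibs show off-diagonals near 0.5.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (normally QC-filtered first).
#' @return a \linkS4class{RelationshipMatrix}.
#' @examples
#' gm <- simulateGenotypes(nFamilies = 5, sibsPerFamily = 2, nUnrelated = 5,
#'                         nSnps = 200, seed = 1)
#' G <- computeGRM(gm)
#' mean(diag(grmValues(G)))
#' @export
computeGRM <- function(gm) {
  d <- dosages(gm)
  p <- alleleFreq(gm)
  p[is.nan(p)] <- 0
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: GRM denominator is zero")
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0  # mean-imputed dosages center to zero
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(d), rownames(d))
  new("RelationshipMatrix", values = G, cache = new.env(parent = emptyenv()))
}

#' Construct a RelationshipMatrix from a plain matrix
#'
#' @param values symmetric numeric matrix with individual ids as dimnames.
#' @return a \linkS4class{RelationshipMatrix}.
#' @export
RelationshipMatrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("ind", seq_len(nrow(values))),
                             paste0("ind", seq_len(nrow(values))))
  new("RelationshipMatrix", values = values,
      cache = new.env(parent = emptyenv()))
}

#' Cached eigendecomposition of a relationship matrix
#'
#' Computed once per object and memoized; reused by the null-model fit (fast
#' path for balanced designs), the scan whitening and polygenic-effect
#' sampling. Eigenvalues below \code{-1e-8 * max} raise an error (the matrix
#' is expected to be PSD after centering); small negatives are clipped to 0.
#'
#' @param grm a \linkS4class{RelationshipMatrix}.
#' @return list with \code{vectors} (n x n) and \code{values} (length n).
#' @export
grmEigen <- function(grm) {
  cache <- grm@cache
  if (!is.null(cache$eigen)) return(cache$eigen)
  e <- eigen(grm@values, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -tol)
    warning("relationship matrix has negative eigenvalues; clipping to 0")
  e$values <- pmax(e$values, 0)
  out <- list(vectors = e$vectors, values = e$values)
  cache$eigen <- out
  out
}

#' Read / write a relationship matrix as TSV
#'
#' Square tab-separated matrix with individual ids as header row and first
#' column.
#'
#' @param grm a \linkS4class{RelationshipMatrix}; @param path file path.
#' @return \code{writeGRM}: the path invisibly; \code{readGRM}: a
#'   \linkS4class{RelationshipMatrix}.
#' @export
writeGRM <- function(grm, path) {
  v <- grmValues(grm)
  out <- data.frame(id = rownames(v), v, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGRM
#' @export
readGRM <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
    check.names = FALSE)
  ids <- as.character(tab[[1L]])
  v <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(v) <- list(ids, ids)
  v <- (v + t(v)) / 2
  RelationshipMatrix(v)
}
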