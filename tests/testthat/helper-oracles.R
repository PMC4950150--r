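# Independent dense-algebra oracles and small fixture builders used across
# the suite. These deliberately use naive loops / explicit inverses so they
# share no code path with the package internals they check.

# brute-force VanRaden G: double loop over individual pairs
bruteGRM <- function(dos) {
  n <- nrow(dos)
  p <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  denom <- 2 * sum(p * (1 - p))
  W <- dos
  for (k in seq_len(ncol(dos))) {
    W[, k] <- dos[, k] - 2 * p[k]
    W[is.na(dos[, k]), k] <- 0
  }
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    G[i, j] <- sum(W[i, ] * W[j, ]) / denom
  G
}

# dense REML criterion via explicit inverses
denseREML <- function(vc, y, X, Z, G) {
  V <- vc[3] * diag(length(y)) + vc[1] * Z %*% G %*% t(Z) +
    vc[2] * tcrossprod(Z)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XVX)$modulus +
    t(y) %*% P %*% y))
}

# dense GLS fit of [X | x] with fixed covariance V; Wald uses the whitened
# residual variance with denominator N - rank, as the scan does
denseGLS <- function(y, X, x, V) {
  Xa <- cbind(X, x)
  Vi <- solve(V)
  XtVi <- t(Xa) %*% Vi
  A <- XtVi %*% Xa
  bhat <- solve(A, XtVi %*% y)
  r <- y - Xa %*% bhat
  rss <- as.numeric(t(r) %*% Vi %*% r)
  df <- length(y) - ncol(Xa)
  s2 <- rss / df
  se <- sqrt(s2 * solve(A)[ncol(Xa), ncol(Xa)])
  beta <- bhat[ncol(Xa)]
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
}

incidenceMatrix <- function(phenoIds, ids) {
  outer(as.character(phenoIds), ids, "==") * 1
}

# small related genotype panel + GRM, shared by several files
smallPanel <- function(seed = 11, nSnps = 300) {
  gm <- simulateGenotypes(nFamilies = 10, sibsPerFamily = 2, nUnrelated = 20,
                          nSnps = nSnps, seed = seed)
  list(gm = gm, grm = computeGRM(gm))
}

writeTinyVCF <- function(path,
                         samples = c("s1", "s2", "s3"),
                         gts = rbind(c("0/0", "0/1", "1/1"),
                                     c("0/1", "./.", "0/0"))) {
  hdr <- c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c("1", 100 * i, paste0("rs", i), "A", "G", ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}
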