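#' Marginal phenotypic covariance of the repeated-measures model
#'
#' V = Z G Z' sigma_g2 + Z Z' sigma_p2 + I_N sigma_e2, the covariance of
#' observations under the model y = X beta + Z g + Z p + e with polygenic
#' effects g ~ N(0, sigma_g2 G), permanent-environment effects
#' p ~ N(0, sigma_p2 I_n) and residuals e ~ N(0, sigma_e2 I_N).
#'
#' @param Z incidence matrix (N observations x n individuals, one 1 per row).
#' @param G genomic relationship matrix (n x n) or a
#'   \linkS4class{RelationshipMatrix}.
#' @param components named numeric with \code{sigma_g2}, \code{sigma_p2},
#'   \code{sigma_e2} (all >= 0, sigma_e2 > 0).
#' @return dense symmetric N x N matrix.
#' @examples
#' Z <- matrix(c(1, 1), 2, 1)   # one individual, two records
#' buildV(Z, matrix(1), c(sigma_g2 = 1, sigma_p2 = 1, sigma_e2 = 1))
#' @export
buildV <- function(Z, G, components) {
  if (is(G, "RelationshipMatrix")) G <- grmValues(G)
  Z <- as.matrix(Z)
  G <- as.matrix(G)
  if (ncol(Z) != nrow(G)) stop("Z columns must match G dimension")
  vc <- checkComponents(components)
  V <- vc["sigma_g2"] * Z %*% G %*% t(Z) +
       vc["sigma_p2"] * tcrossprod(Z) +
       diag(vc["sigma_e2"], nrow(Z))
  (V + t(V)) / 2
}

checkComponents <- function(components) {
  need <- c("sigma_g2", "sigma_p2", "sigma_e2")
  if (is.null(names(components)) && length(components) == 3)
    names(components) <- need
  if (!all(need %in% names(components)))
    stop("components must be named sigma_g2, sigma_p2, sigma_e2")
  vc <- components[need]
  if (any(!is.finite(vc)) || any(vc < 0) || vc["sigma_e2"] <= 0)
    stop("variance components must be finite, non-negative, sigma_e2 > 0")
  vc
}

# --- internal REML engine -------------------------------------------------
#
# V = Z A Z' + sigma_e2 I with A = sigma_g2 G + sigma_p2 I (n x n). With
# B = Z D^{-1/2} (orthonormal, D = Z'Z diagonal) and Ms = D^{1/2} A D^{1/2}:
#   V^{-1} v    = (1/se2) [v - B Ms (Ms + se2 I)^{-1} B' v]
#   log|V|      = (N - n) log se2 + log|Ms + se2 I|
# so every REML evaluation needs only n x n algebra. For balanced designs
# (D = r I) Ms diagonalizes in the fixed eigenbasis of G, making each
# evaluation O(n p^2) after one eigendecomposition of G (memoized on the
# RelationshipMatrix).

remlPrep <- function(y, X, zIndex, G, grmObj = NULL) {
  N <- length(y)
  n <- nrow(G)
  counts <- tabulate(zIndex, nbins = n)
  if (any(counts == 0)) stop("internal: individuals without observations")
  dh <- sqrt(counts)
  Zty <- rowsum(y, zIndex)[, 1]
  ZtX <- rowsum(X, zIndex)
  by <- Zty / dh
  BX <- ZtX / dh
  balanced <- length(unique(counts)) == 1L
  prep <- list(N = N, n = n, counts = counts, dh = dh,
    yy = sum(y * y), Xy = crossprod(X, y), XX = crossprod(X),
    by = by, BX = BX, G = G, balanced = balanced, p = ncol(X))
  if (balanced) {
    eg <- if (!is.null(grmObj) && nrow(grmValues(grmObj)) == n) grmEigen(grmObj)
          else {
            e <- eigen(G, symmetric = TRUE)
            list(vectors = e$vectors, values = pmax(e$values, 0))
          }
    prep$r <- counts[1]
    prep$d <- eg$values
    prep$E <- eg$vectors
    prep$uy <- crossprod(eg$vectors, by)[, 1]
    prep$UX <- crossprod(eg$vectors, BX)
  }
  prep
}

# restricted log-likelihood (up to an additive constant) and GLS beta
remlEval <- function(prep, sg2, sp2, se2, want_beta = FALSE) {
  N <- prep$N; n <- prep$n; p <- prep$p
  if (prep$balanced) {
    S <- prep$r * (sg2 * prep$d + sp2)
    w <- S / (S + se2)
    yVy <- (prep$yy - sum(w * prep$uy^2)) / se2
    XVX <- (prep$XX - crossprod(prep$UX, w * prep$UX)) / se2
    XVy <- (prep$Xy - crossprod(prep$UX, w * prep$uy)) / se2
    logdetV <- (N - n) * log(se2) + sum(log(S + se2))
  } else {
    A <- sg2 * prep$G
    diag(A) <- diag(A) + sp2
    K <- outer(prep$dh, prep$dh) * A
    diag(K) <- diag(K) + se2
    cK <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(cK)) return(list(ll = -Inf))
    rhs <- cbind(prep$by, prep$BX)
    Kirhs <- backsolve(cK, forwardsolve(t(cK), rhs))
    Kiy <- Kirhs[, 1]
    KiX <- Kirhs[, -1, drop = FALSE]
    # v'V^{-1}w = (1/se2)(v'w - bv'bw) + bv' K^{-1} bw
    yVy <- (prep$yy - sum(prep$by^2)) / se2 + sum(prep$by * Kiy)
    XVX <- (prep$XX - crossprod(prep$BX)) / se2 + crossprod(prep$BX, KiX)
    XVy <- (prep$Xy - crossprod(prep$BX, prep$by)) / se2 +
      crossprod(prep$BX, Kiy)
    logdetV <- (N - n) * log(se2) + 2 * sum(log(diag(cK)))
  }
  cX <- tryCatch(chol((XVX + t(XVX)) / 2), error = function(e) NULL)
  if (is.null(cX)) return(list(ll = -Inf))
  beta <- backsolve(cX, forwardsolve(t(cX), XVy))
  yPy <- yVy - sum(XVy * beta)
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(cX))) + yPy)
  out <- list(ll = as.numeric(ll))
  if (want_beta) out$beta <- beta[, 1]
  out
}

#' Restricted log-likelihood of the repeated-measures model
#'
#' The REML criterion -0.5 [log|V| + log|X'V^{-1}X| + y'Py] (up to an additive
#' constant), with V as in [buildV()] and P the REML projection matrix. This
#' is the objective maximized by [fitNull()]; evaluations use the low-rank
#' factorization of V, never a dense N x N inverse.
#'
#' @inheritParams buildV
#' @param y response vector (length N).
#' @param X fixed-effect design matrix (N x p, full rank).
#' @return the restricted log-likelihood (scalar).
#' @export
remlLogLik <- function(components, y, X, Z, G) {
  vc <- checkComponents(components)
  if (is(G, "RelationshipMatrix")) G <- grmValues(G)
  Z <- as.matrix(Z)
  if (!all(Z %in% c(0, 1)) || any(rowSums(Z) != 1))
    stop("Z must be an incidence matrix with exactly one 1 per row")
  zIndex <- max.col(Z)
  used <- sort(unique(zIndex))
  if (length(used) < ncol(Z)) {
    G <- G[used, used, drop = FALSE]
    zIndex <- match(zIndex, used)
  }
  prep <- remlPrep(y, as.matrix(X), zIndex, G)
  remlEval(prep, vc["sigma_g2"], vc["sigma_p2"], vc["sigma_e2"])$ll
}

#' Fit the SNP-free repeated-measures mixed model by REML
#'
#' Stage 1 of the two-stage association method: estimates the variance
#' components (sigma_g2, sigma_p2, sigma_e2) of
#' y = X beta + Z g + Z p + e by REML and returns the fitted null model,
#' including the factorized phenotypic covariance V0 used to whiten the
#' per-SNP scans. Optimization is by L-BFGS-B on log-variance parameters
#' (start: each component = var(residuals of the fixed-effect fit) / 3; lower
#' bound 1e-8 x var(y), reported as a boundary flag and a 0 estimate).
#'
#' @param pheno observation-level data.frame with columns \code{id},
#'   \code{trait}, plus any covariates referenced by \code{fixed}.
#' @param fixed one-sided formula for the fixed effects (default \code{~ 1});
#'   categorical covariates are dummy-coded with first-level reference.
#' @param grm a \linkS4class{RelationshipMatrix} covering every phenotyped id.
#' @param permEnv include the permanent-environment component (default TRUE).
#'   Set FALSE for single-record models such as the individual-averages
#'   baseline, where sigma_p2 is not separable from sigma_e2.
#' @param maxit maximum optimizer iterations.
#' @return a \linkS4class{NullFit}.
#' @examples
#' gm <- simulateGenotypes(nFamilies = 20, sibsPerFamily = 2, nUnrelated = 20,
#'                         nSnps = 300, seed = 7)
#' G <- computeGRM(gm)
#' sim <- simulateGaussian(gm, components = c(1, 1, 1),
#'                         design = designSpec("balanced", 2), seed = 7,
#'                         grm = G)
#' fitNull(sim$pheno, ~ 1, G)
#' @export
fitNull <- function(pheno, fixed = ~ 1, grm, permEnv = TRUE, maxit = 200L) {
  stopifnot(is.data.frame(pheno), all(c("id", "trait") %in% names(pheno)))
  y <- as.numeric(pheno$trait)
  if (any(!is.finite(y))) stop("trait values must be finite")
  gIds <- individualIds(grm)
  bad <- setdiff(unique(as.character(pheno$id)), gIds)
  if (length(bad))
    stop("phenotyped ids missing from relationship matrix: ",
         paste(utils::head(bad, 5), collapse = ", "))
  usedIds <- gIds[gIds %in% pheno$id]
  zIndex <- match(as.character(pheno$id), usedIds)
  n <- length(usedIds)
  N <- length(y)
  if (n < 2) stop("need at least two individuals")

  X <- stats::model.matrix(fixed, data = pheno)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }

  full <- length(usedIds) == length(gIds)
  Gsub <- if (full) grmValues(grm) else grmValues(grm)[usedIds, usedIds]
  prep <- remlPrep(y, X, zIndex, Gsub, grmObj = if (full) grm else NULL)

  counts <- prep$counts
  if (permEnv && all(counts == 1L))
    warning("single record per individual: sigma_p2 is not separable from ",
            "sigma_e2 (only their sum is identified); consider permEnv = FALSE")

  vy <- stats::var(y)
  resid0 <- stats::lm.fit(X, y)$residuals
  start <- max(stats::var(resid0), 1e-6) / 3
  floorv <- 1e-8 * max(vy, 1e-12)

  if (permEnv) {
    obj <- function(th) {
      v <- exp(th)
      ll <- remlEval(prep, v[1], v[2], v[3])$ll
      if (!is.finite(ll)) 1e10 else -ll  # keep L-BFGS-B on finite ground
    }
    th0 <- rep(log(start), 3)
  } else {
    obj <- function(th) {
      v <- exp(th)
      ll <- remlEval(prep, v[1], 0, v[2])$ll
      if (!is.finite(ll)) 1e10 else -ll
    }
    th0 <- rep(log(start), 2)
  }
  lower <- rep(log(floorv), length(th0))
  upper <- rep(log(1e6 * max(vy, 1)), length(th0))
  opt <- stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
    upper = upper, control = list(maxit = maxit, factr = 1e4))
  if (opt$convergence == 1L)
    stop("REML did not converge within ", maxit, " iterations ",
         "(criterion ", format(-opt$value), ", evaluations ",
         opt$counts[1], ")")
  v <- exp(opt$par)
  atFloor <- opt$par <= lower + 1e-6
  if (permEnv) {
    vc <- c(sigma_g2 = v[1], sigma_p2 = v[2], sigma_e2 = v[3])
    boundary <- atFloor
  } else {
    vc <- c(sigma_g2 = v[1], sigma_p2 = 0, sigma_e2 = v[2])
    boundary <- c(atFloor[1], FALSE, atFloor[2])
  }
  names(boundary) <- names(vc)
  vc[c("sigma_g2", "sigma_p2")][boundary[c(1, 2)]] <- 0
  vc["sigma_e2"] <- max(vc["sigma_e2"], floorv)

  fin <- remlEval(prep, vc["sigma_g2"], vc["sigma_p2"], vc["sigma_e2"],
                  want_beta = TRUE)
  beta <- fin$beta
  names(beta) <- colnames(X)

  # eigenbasis of Ms = D^{1/2} A D^{1/2} at the estimates
  if (prep$balanced) {
    Q <- prep$E
    S <- prep$r * (vc["sigma_g2"] * prep$d + vc["sigma_p2"])
  } else {
    A <- vc["sigma_g2"] * Gsub
    diag(A) <- diag(A) + vc["sigma_p2"]
    Ms <- outer(prep$dh, prep$dh) * A
    e <- eigen((Ms + t(Ms)) / 2, symmetric = TRUE)
    Q <- e$vectors
    S <- pmax(e$values, 0)
  }

  new("NullFit", components = vc, boundary = boundary, betaFixed = beta,
    loglikREML = fin$ll, zIndex = as.integer(zIndex),
    counts = as.integer(counts), Q = Q, S = as.numeric(S),
    X = X, y = y, individualIds = usedIds)
}

#' Reconstruct the dense null covariance V0
#'
#' Rebuilds V0 = Z G Z' sigma_g2 + Z Z' sigma_p2 + I sigma_e2 from the
#' factorization stored in a \linkS4class{NullFit}. Intended for inspection
#' and verification on small problems (the matrix is N x N).
#'
#' @param fit a \linkS4class{NullFit}.
#' @return dense symmetric N x N matrix.
#' @export
nullCovariance <- function(fit) {
  n <- length(fit@counts)
  N <- length(fit@y)
  B <- matrix(0, N, n)
  B[cbind(seq_len(N), fit@zIndex)] <- 1 / sqrt(fit@counts[fit@zIndex])
  core <- fit@Q %*% (fit@S * t(fit@Q))
  V <- B %*% core %*% t(B)
  diag(V) <- diag(V) + fit@components["sigma_e2"]
  (V + t(V)) / 2
}
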