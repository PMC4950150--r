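test_that("the rotation whitens the fitted covariance", {
  pan <- smallPanel(seed = 81)
  sim <- simulateGaussian(pan$gm, components = c(1, 1, 1),
    design = designSpec("unbalanced"), seed = 82, grm = pan$grm)
  fit <- fitNull(sim$pheno, ~ 1, pan$grm)
  op <- makeRotation(fit)
  V0 <- nullCovariance(fit)
  N <- nrow(V0)
  R <- rotate(op, diag(N))
  expect_lt(max(abs(R %*% V0 %*% t(R) - diag(N))), 1e-6)
})

test_that("scan equals dense GLS with explicit V0 inverse (small instances)", {
  for (seed in c(91, 92)) {
    gm <- simulateGenotypes(nFamilies = 5, sibsPerFamily = 2, nUnrelated = 8,
                            nSnps = 25, mafLow = 0.15, seed = seed)
    grm <- computeGRM(gm)
    sim <- simulateGaussian(gm, qtlIndices = 3, qtlEffects = 1,
      components = c(1, 0.5, 1), design = designSpec("unbalanced"),
      seed = seed + 1, grm = grm)
    fit <- fitNull(sim$pheno, ~ 1, grm)
    scan <- rglsScan(gm, fit)
    tab <- scanTable(scan)

    ids <- fit@individualIds
    Z <- incidenceMatrix(sim$pheno$id, ids)
    V0 <- buildV(Z, grmValues(grm)[ids, ids], varComp(fit))
    D <- dosages(gm)[match(ids, individualIds(gm)), ]
    X <- matrix(1, nrow(Z), 1)
    for (j in seq_len(nSnps(gm))) {
      if (tab$excluded[j]) next
      xj <- D[, j]
      if (anyNA(xj)) xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
      ref <- denseGLS(fit@y, X, Z %*% xj, V0)
      expect_equal(tab$beta[j], ref$beta, tolerance = 1e-8)
      expect_equal(tab$se[j], ref$se, tolerance = 1e-8)
      expect_equal(tab$p[j], ref$p, tolerance = 1e-8)
    }
  }
})

test_that("with V0 = I the scan reduces to per-SNP ordinary least squares", {
  set.seed(101)
  n <- 35
  ids <- paste0("i", 1:n)
  dos <- matrix(rbinom(n * 12, 2, 0.4), n, 12, dimnames = list(ids, NULL))
  gm <- GenotypeMatrix(dos)
  y <- rnorm(n)
  pheno <- data.frame(id = ids, trait = y)
  fit <- rmgwas:::olsNullFit(pheno, ~ 1, RelationshipMatrix(
    `dimnames<-`(diag(n), list(ids, ids))))
  tab <- scanTable(rglsScan(gm, fit))
  for (j in 1:12) {
    lmf <- summary(lm(y ~ dos[, j]))$coefficients
    expect_equal(tab$beta[j], lmf[2, 1], tolerance = 1e-10)
    expect_equal(tab$se[j], lmf[2, 2], tolerance = 1e-10)
    expect_equal(tab$p[j], 2 * pnorm(-abs(lmf[2, 3])), tolerance = 1e-10)
  }
})

test_that("allele-coding flip negates beta and preserves p", {
  pan <- smallPanel(seed = 111, nSnps = 40)
  sim <- simulateGaussian(pan$gm, components = c(1, 1, 1),
    design = designSpec("balanced", 2), seed = 112, grm = pan$grm)
  fit <- fitNull(sim$pheno, ~ 1, pan$grm)
  tab1 <- scanTable(rglsScan(pan$gm, fit))

  flipped <- 2 - dosages(pan$gm)
  gm2 <- GenotypeMatrix(flipped, snpInfo = as.data.frame(snpInfo(pan$gm)))
  tab2 <- scanTable(rglsScan(gm2, fit))
  ok <- !tab1$excluded
  expect_equal(tab2$beta[ok], -tab1$beta[ok], tolerance = 1e-10)
  expect_equal(tab2$p[ok], tab1$p[ok], tolerance = 1e-10)
})

test_that("shifting the trait or permuting inputs does not change the tests", {
  pan <- smallPanel(seed = 121, nSnps = 40)
  sim <- simulateGaussian(pan$gm, components = c(1, 1, 1),
    design = designSpec("balanced", 2), seed = 122, grm = pan$grm)
  fit <- fitNull(sim$pheno, ~ 1, pan$grm)
  tab <- scanTable(rglsScan(pan$gm, fit))

  shifted <- sim$pheno; shifted$trait <- shifted$trait + 11
  fitS <- fitNull(shifted, ~ 1, pan$grm)
  tabS <- scanTable(rglsScan(pan$gm, fitS))
  expect_equal(tabS$beta, tab$beta, tolerance = 1e-6)
  expect_equal(tabS$p, tab$p, tolerance = 1e-6)
  expect_equal(unname(fixef(fitS)[1] - fixef(fit)[1]), 11, tolerance = 1e-6)

  # permuting SNP columns permutes results
  perm <- sample(nSnps(pan$gm))
  tabP <- scanTable(rglsScan(pan$gm[, perm], fit))
  expect_equal(tabP$beta, tab$beta[perm], tolerance = 1e-10)

  # permuting observation rows leaves results unchanged
  rperm <- sample(nrow(sim$pheno))
  fitR <- fitNull(sim$pheno[rperm, ], ~ 1, pan$grm)
  tabR <- scanTable(rglsScan(pan$gm, fitR))
  expect_equal(tabR$p, tab$p, tolerance = 1e-6)
})

test_that("zero-variance SNPs are flagged and excluded from lambda", {
  pan <- smallPanel(seed = 131, nSnps = 30)
  dos <- dosages(pan$gm)
  dos[, 5] <- 1  # monomorphic column
  gm <- GenotypeMatrix(dos)
  grm <- computeGRM(gm)
  sim <- simulateGaussian(gm, components = c(1, 1, 1),
    design = designSpec("balanced", 2), seed = 132, grm = grm)
  fit <- fitNull(sim$pheno, ~ 1, grm)
  tab <- scanTable(rglsScan(gm, fit))
  expect_true(tab$excluded[5])
  expect_true(is.na(tab$p[5]))
})

test_that("Wald p-values match the standard normal tail", {
  expect_equal(waldP(0), 1)
  expect_equal(waldP(1.959964), 0.05, tolerance = 1e-6)
  # quadrature oracle for the tail mass
  for (z in c(0.5, 1.3, 2.7, 4.2, 6)) {
    tail <- integrate(dnorm, z, Inf, rel.tol = 1e-12)$value
    expect_equal(waldP(z), 2 * tail, tolerance = 1e-6)
    expect_equal(waldP(-z), waldP(z))
  }
  expect_gt(waldP(40), 0)  # stays in (0, 1]
})

test_that("inflation factor: null calibration, monotonicity, construction", {
  m <- 9999
  pUnif <- (1:m) / (m + 1)
  expect_equal(inflationLambda(pUnif), 1.0, tolerance = 0.01)
  expect_gt(inflationLambda(pUnif / 2), 1)

  set.seed(141)
  chi <- rchisq(10000, 1) * 1.2
  pInfl <- pchisq(chi, 1, lower.tail = FALSE)
  expect_equal(inflationLambda(pInfl), 1.2, tolerance = 0.03)
  expect_equal(inflationLambda(pInfl, method = "regression"), 1.2,
               tolerance = 0.05)
  expect_error(inflationLambda(runif(5)), "at least 10")
})
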