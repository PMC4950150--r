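test_that("balanced designs give exact counts; unbalanced matches Poisson(2)", {
  des <- makeDesign(paste0("i", 1:10), designSpec("balanced", 2), seed = 1)
  expect_equal(nrow(des), 20L)
  expect_true(all(table(des$id) == 2))

  des2 <- makeDesign(paste0("i", 1:10), designSpec("balanced", 2), seed = 1)
  expect_identical(des, des2)

  # unbalanced: mean ~ 2, variance ~ 2 (counting individuals that drew 0)
  n <- 10000
  set.seed(2)
  desU <- makeDesign(paste0("i", 1:n), designSpec("unbalanced"), seed = NULL)
  counts <- table(factor(desU$id, levels = paste0("i", 1:n)))
  expect_gt(mean(counts), 1.96); expect_lt(mean(counts), 2.04)
  expect_gt(var(as.numeric(counts)), 1.9); expect_lt(var(as.numeric(counts)), 2.1)

  # years are not repeated within an individual when avoidable
  des3 <- makeDesign("solo", designSpec("balanced", 8, nYears = 10), seed = 3)
  expect_equal(anyDuplicated(des3$year), 0L)
})

test_that("all-zero components with no QTL give identically zero phenotypes", {
  pan <- smallPanel(seed = 151, nSnps = 50)
  sim <- simulateGaussian(pan$gm, components = c(0, 0, 1e-12),
    design = designSpec("balanced", 2), seed = 152, grm = pan$grm)
  expect_lt(max(abs(sim$pheno$trait)), 1e-5)
})

test_that("repeat records are identical when only genetic variance is present", {
  pan <- smallPanel(seed = 161, nSnps = 50)
  sim <- simulateGaussian(pan$gm, components = c(1, 0, 1e-12),
    design = designSpec("balanced", 3), seed = 162, grm = pan$grm)
  spread <- tapply(sim$pheno$trait, sim$pheno$id, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-5)
})

test_that("realized phenotypic variance decomposes as expected", {
  gm <- simulateGenotypes(nFamilies = 50, sibsPerFamily = 2, nUnrelated = 100,
                          nSnps = 500, mafLow = 0.05, seed = 171)
  grm <- computeGRM(gm)
  q <- which.max(minorAlleleFreq(gm))
  p <- unname(alleleFreq(gm)[q])
  vtot <- replicate(50, {
    sim <- simulateGaussian(gm, qtlIndices = q, qtlEffects = 0.5,
      components = c(1, 1, 1), design = designSpec("balanced", 2),
      seed = NULL, grm = grm)
    var(sim$pheno$trait)
  })
  expected <- 3 + 0.25 * 2 * p * (1 - p)
  expect_equal(mean(vtot), expected, tolerance = 0.05)
})

test_that("year effects contribute their intended variance share", {
  gm <- simulateGenotypes(nFamilies = 50, sibsPerFamily = 2, nUnrelated = 100,
                          nSnps = 400, mafLow = 0.05, seed = 181)
  grm <- computeGRM(gm)
  shares <- replicate(40, {
    sim <- simulateGaussian(gm, components = c(1, 1, 1),
      design = designSpec("unbalanced", nYears = 10), yearVariance = 4,
      seed = NULL, grm = grm)
    fitY <- lm(trait ~ factor(year), data = sim$pheno)
    anova(fitY)[1, "Sum Sq"] / sum(anova(fitY)[, "Sum Sq"])
  })
  # sigma_year^2 = 4 against 3 from the components: share ~ 4/7 = 0.57
  expect_gt(mean(shares), 0.50)
  expect_lt(mean(shares), 0.64)
})

test_that("binary thresholding: degenerate taus, symmetry, tail probability", {
  pan <- smallPanel(seed = 191, nSnps = 50)
  simAll1 <- simulateBinary(pan$gm, components = c(1, 1, 1),
    design = designSpec("balanced", 2), tau = -Inf, seed = 192, grm = pan$grm)
  expect_true(all(simAll1$pheno$trait == 1))
  simAll0 <- simulateBinary(pan$gm, components = c(1, 1, 1),
    design = designSpec("balanced", 2), tau = Inf, seed = 192, grm = pan$grm)
  expect_true(all(simAll0$pheno$trait == 0))

  # tau = 0, no QTL: half ones at 10,000 observations
  gmBig <- simulateGenotypes(nFamilies = 0, nUnrelated = 5000, nSnps = 60,
                             mafLow = 0.1, seed = 193)
  simHalf <- simulateBinary(gmBig, components = c(1, 1, 1),
    design = designSpec("balanced", 2), tau = 0, seed = 194)
  expect_equal(mean(simHalf$pheno$trait), 0.5, tolerance = 0.04)

  # fraction of ones matches the Gaussian tail implied by (tau, variance)
  simT <- simulateBinary(gmBig, components = c(1, 1, 1),
    design = designSpec("balanced", 2), tau = -1, seed = 195)
  expect_equal(mean(simT$pheno$trait), pnorm(1 / sqrt(3)), tolerance = 0.02)

  # liabilities and threshold are retained and consistent
  expect_equal(as.numeric(simT$truth@liability > simT$truth@tau),
               simT$pheno$trait)
})

test_that("simulation output is deterministic per seed and written faithfully", {
  pan <- smallPanel(seed = 201, nSnps = 40)
  s1 <- simulateGaussian(pan$gm, components = c(1, 1, 1),
    design = designSpec("unbalanced"), yearVariance = 1, seed = 7, grm = pan$grm)
  s2 <- simulateGaussian(pan$gm, components = c(1, 1, 1),
    design = designSpec("unbalanced"), yearVariance = 1, seed = 7, grm = pan$grm)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth@g, s2$truth@g)

  pp <- tempfile(fileext = ".tsv"); tp <- tempfile(fileext = ".json")
  writeSimulation(s1, pp, tp)
  back <- read.table(pp, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(s1$pheno))
  meta <- jsonlite::read_json(tp)
  expect_equal(meta$seed, 7)
  expect_equal(unlist(meta$components), s1$truth@components,
               ignore_attr = TRUE)
})
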