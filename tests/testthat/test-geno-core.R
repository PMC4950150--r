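test_that("VCF reading counts ALT alleles, handles missing and round-trips", {
  vcf <- writeTinyVCF(tempfile(fileext = ".vcf"))
  gm <- readVCF(vcf)
  expect_s4_class(gm, "GenotypeMatrix")
  d <- dosages(gm)
  expect_equal(unname(d[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(d["s1", "rs2"]), 1)
  expect_true(is.na(d["s2", "rs2"]))
  expect_equal(snpInfo(gm)$pos, c(100L, 200L))

  # single sample, single het site
  v1 <- writeTinyVCF(tempfile(fileext = ".vcf"), samples = "only",
                     gts = matrix("0/1", 1, 1))
  expect_equal(unname(dosages(readVCF(v1))[1, 1]), 1)

  # write a dosage table from the VCF and read it back
  tsv <- tempfile(fileext = ".tsv")
  writeDosageTable(gm, tsv)
  gm2 <- readDosageTable(tsv)
  expect_identical(dosages(gm2), dosages(gm))
})

test_that("multi-allelic sites are skipped with a warning", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "100", "m1", "A", "G,T", ".", ".", ".", "GT", "1/2"),
          collapse = "\t"),
    paste(c("1", "200", "b1", "A", "G", ".", ".", ".", "GT", "1/1"),
          collapse = "\t")), path)
  expect_warning(gm <- readVCF(path), "multi-allelic")
  expect_equal(nSnps(gm), 1L)
  expect_equal(snpInfo(gm)$id, "b1")
})

test_that("dosage table parsing rejects invalid entries and maps NA", {
  tab <- "id\tsnpA\tsnpB\nind1\t0\t2\nind2\t1\tNA\n"
  f <- tempfile(); writeLines(tab, f)
  gm <- readDosageTable(f)
  expect_equal(unname(dosages(gm)[1, ]), c(0, 2))
  expect_true(is.na(dosages(gm)["ind2", "snpB"]))

  bad <- tempfile(); writeLines("id\ts1\nind1\t3\n", bad)
  expect_error(readDosageTable(bad), "invalid dosage")
})

test_that("allele frequency matches naive counting and is order-invariant", {
  gm <- GenotypeMatrix(matrix(c(0, 1, 2, 2, 2, 2), 3, 2,
    dimnames = list(letters[1:3], c("a1", "a2"))))
  expect_equal(unname(alleleFreq(gm)), c(0.5, 1.0))
  expect_equal(unname(minorAlleleFreq(gm)), c(0.5, 0.0))

  set.seed(42)
  dos <- matrix(sample(c(0, 1, 2, NA), 200, replace = TRUE,
                       prob = c(.4, .3, .2, .1)), 100, 2)
  rownames(dos) <- paste0("i", 1:100)
  gm <- GenotypeMatrix(dos)
  naive <- apply(dos, 2, function(v) sum(v, na.rm = TRUE) / (2 * sum(!is.na(v))))
  expect_equal(unname(alleleFreq(gm)), unname(naive))
  perm <- sample(100)
  expect_equal(unname(alleleFreq(gm[perm, ])), unname(alleleFreq(gm)))
})

test_that("HWE chi-square test: perfect fit, disequilibrium, hand-computed", {
  expect_equal(hweTest(25, 50, 25), 1)
  expect_lt(hweTest(50, 0, 50), 1e-10)
  # hand-computed at p = 0.5: expected (25, 50, 25), stat = 25/25+100/50+25/25
  stat <- (30 - 25)^2 / 25 + (40 - 50)^2 / 50 + (30 - 25)^2 / 25
  expect_equal(hweTest(30, 40, 30), pchisq(stat, 1, lower.tail = FALSE))
  # monomorphic convention
  expect_equal(hweTest(80, 0, 0), 1)
})

test_that("HWE p-values are uniform under the null", {
  set.seed(7)
  nInd <- 500; m <- 2000
  p <- runif(m, 0.1, 0.5)
  frac <- vapply(seq_len(m), function(k) {
    g <- rbinom(nInd, 2, p[k])
    hweTest(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  expect_gt(mean(frac < 0.05), 0.03)
  expect_lt(mean(frac < 0.05), 0.07)
})

test_that("QC filter applies the three rules and counts failures", {
  set.seed(3)
  n <- 60
  # 100 well-behaved SNPs, then planted failures
  dos <- sapply(1:100, function(k) rbinom(n, 2, runif(1, 0.2, 0.5)))
  lowCall <- c(rbinom(n - 10, 2, 0.4), rep(NA, 10))        # call rate 5/6
  rare <- c(1, rep(0, n - 1))                               # maf ~ 0.008
  hweBad <- rep(c(0, 2), n / 2)                             # no hets
  dos <- cbind(dos, lowCall, rare, hweBad)
  rownames(dos) <- paste0("i", seq_len(n))
  gm <- GenotypeMatrix(dos)

  res <- qcFilter(gm)
  rep <- res$report
  expect_s4_class(rep, "QCReport")
  expect_equal(rep@nInput, 103L)
  expect_gte(rep@nFailedCallRate, 1L)
  expect_gte(rep@nFailedMaf, 1L)
  expect_gte(rep@nFailedHwe, 1L)
  # independent per-rule recount
  cr <- colMeans(!is.na(dos))
  f <- apply(dos, 2, function(v) sum(v, na.rm = TRUE) / (2 * sum(!is.na(v))))
  maf <- pmin(f, 1 - f)
  hwe <- apply(dos, 2, function(v)
    hweTest(sum(v == 0, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
            sum(v == 2, na.rm = TRUE)))
  keep <- cr >= 0.95 & maf >= 0.01 & hwe > 0.001
  expect_equal(rep@nPassed, sum(keep))
  expect_equal(nSnps(res$genotypes), sum(keep))

  # idempotence: filtering the filtered matrix removes nothing
  res2 <- qcFilter(res$genotypes)
  expect_equal(res2$report@nPassed, res2$report@nInput)
})

test_that("GRM: closed forms, brute-force equivalence, permutation", {
  # single SNP, p = 0.5, dosages (0, 2): G = [[2,-2],[-2,2]]
  gm <- GenotypeMatrix(matrix(c(0, 2), 2, 1,
    dimnames = list(c("a", "b"), "s")))
  expect_equal(unname(grmValues(computeGRM(gm))),
               matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  # identical genotype rows: G12 = G11 = G22
  gm2 <- GenotypeMatrix(rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1),
                              c = c(2, 1, 0, 1)))
  G2 <- grmValues(computeGRM(gm2))
  expect_equal(G2[1, 2], G2[1, 1])
  expect_equal(G2[1, 2], G2[2, 2])

  # brute-force double loop, with missing values
  set.seed(9)
  dos <- matrix(sample(c(0, 1, 2, NA), 20 * 50, TRUE, c(.4, .3, .25, .05)),
                20, 50, dimnames = list(paste0("i", 1:20), NULL))
  gm3 <- GenotypeMatrix(dos)
  G3 <- grmValues(computeGRM(gm3))
  expect_equal(G3, bruteGRM(dos), tolerance = 1e-10, ignore_attr = TRUE)

  # symmetry and PSD-ness after clipping
  expect_lt(max(abs(G3 - t(G3))), 1e-10)
  expect_gt(min(eigen(G3, symmetric = TRUE)$values), -1e-8)

  # permutation equivariance
  perm <- sample(20)
  G3p <- grmValues(computeGRM(gm3[perm, ]))
  expect_equal(G3p, G3[perm, perm], tolerance = 1e-12)

  expect_error(computeGRM(GenotypeMatrix(matrix(2, 3, 2))), "monomorphic")
})

test_that("simulated genotypes: determinism, sib relatedness, LLN", {
  gm1 <- simulateGenotypes(nFamilies = 50, sibsPerFamily = 2, nSnps = 1000,
                           mafLow = 0.1, seed = 5)
  gm2 <- simulateGenotypes(nFamilies = 50, sibsPerFamily = 2, nSnps = 1000,
                           mafLow = 0.1, seed = 5)
  expect_identical(dosages(gm1), dosages(gm2))

  G <- grmValues(computeGRM(gm1))
  sibPairs <- cbind(seq(1, 99, 2), seq(2, 100, 2))
  expect_gt(mean(G[sibPairs]), 0.4)
  expect_lt(mean(G[sibPairs]), 0.6)

  # unrelated-only: mean |off-diagonal| shrinks with the number of SNPs
  gmU <- simulateGenotypes(nFamilies = 0, nUnrelated = 40, nSnps = 5000,
                           mafLow = 0.1, seed = 6)
  GU <- grmValues(computeGRM(gmU))
  off <- abs(GU[upper.tri(GU)])
  expect_lte(mean(off), 0.05)
})
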