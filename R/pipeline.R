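#' End-to-end association scan from files
#'
#' Reads genotypes (VCF or dosage TSV) and a long-format phenotype table,
#' applies SNP QC, builds the GRM (or reads a precomputed one), fits the
#' null repeated-measures model, scans every SNP and writes the results:
#' \code{<prefix>_scan.tsv}, \code{<prefix>_qq.png},
#' \code{<prefix>_manhattan.png} and \code{<prefix>_log.txt}.
#'
#' @param genotypeFile VCF (\code{.vcf}/\code{.vcf.gz}) or dosage TSV.
#' @param phenotypeFile TSV with columns \code{id}, \code{trait} and any
#'   covariates.
#' @param outPrefix path prefix for outputs.
#' @param fixed one-sided fixed-effects formula (default \code{~ 1}).
#' @param grmFile optional precomputed GRM TSV (else computed from the
#'   post-QC genotypes).
#' @param minCallRate,minMaf,minHweP QC thresholds (see [qcFilter()]).
#' @param identityV0 if TRUE, skip the mixed model and scan with V0 = I,
#'   i.e. plain ordinary least squares per SNP.
#' @param plots write QQ/Manhattan PNGs (default TRUE).
#' @return invisibly, a list with the scan, the null fit (or NULL) and the
#'   QC report.
#' @export
runScan <- function(genotypeFile, phenotypeFile, outPrefix,
                    fixed = ~ 1, grmFile = NULL,
                    minCallRate = 0.95, minMaf = 0.01, minHweP = 0.001,
                    identityV0 = FALSE, plots = TRUE) {
  t0 <- Sys.time()
  if (!file.exists(phenotypeFile))
    stop("phenotype file not found: ", phenotypeFile)
  if (!file.exists(genotypeFile))
    stop("genotype file not found: ", genotypeFile)
  gm <- if (grepl("\\.vcf(\\.gz)?$", genotypeFile)) readVCF(genotypeFile)
        else readDosageTable(genotypeFile)
  pheno <- utils::read.table(phenotypeFile, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE)
  if (!all(c("id", "trait") %in% names(pheno)))
    stop("phenotype file needs columns 'id' and 'trait'")
  pheno$id <- as.character(pheno$id)

  qc <- qcFilter(gm, minCallRate, minMaf, minHweP)
  gm <- qc$genotypes
  grm <- if (!is.null(grmFile)) readGRM(grmFile) else computeGRM(gm)

  if (identityV0) {
    fit <- olsNullFit(pheno, fixed, grm)
  } else {
    fit <- fitNull(pheno, fixed, grm)
  }
  scan <- rglsScan(gm, fit)
  writeScanTable(scan, paste0(outPrefix, "_scan.tsv"))
  if (plots) {
    qqPlot(scan, paste0(outPrefix, "_qq.png"))
    manhattanPlot(scan, paste0(outPrefix, "_manhattan.png"))
  }
  vc <- varComp(fit)
  log <- c(
    sprintf("genotypes: %s (%d SNPs post-QC of %d)", genotypeFile,
            qc$report@nPassed, qc$report@nInput),
    sprintf("phenotypes: %s (N=%d observations, n=%d individuals)",
            phenotypeFile, nrow(pheno), length(unique(pheno$id))),
    sprintf("variance components: sigma_g2=%.4g sigma_p2=%.4g sigma_e2=%.4g",
            vc["sigma_g2"], vc["sigma_p2"], vc["sigma_e2"]),
    sprintf("lambda: %.4f", lambdaGC(scan)),
    sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log, paste0(outPrefix, "_log.txt"))
  invisible(list(scan = scan, fit = fit, qc = qc$report))
}

# a NullFit describing V0 = I (scan then reduces to per-SNP OLS)
olsNullFit <- function(pheno, fixed, grm) {
  ids <- individualIds(grm)
  usedIds <- ids[ids %in% pheno$id]
  zIndex <- match(as.character(pheno$id), usedIds)
  counts <- tabulate(zIndex, nbins = length(usedIds))
  X <- stats::model.matrix(fixed, data = pheno)
  y <- as.numeric(pheno$trait)
  new("NullFit",
    components = c(sigma_g2 = 0, sigma_p2 = 0, sigma_e2 = 1),
    boundary = c(sigma_g2 = TRUE, sigma_p2 = TRUE, sigma_e2 = FALSE),
    betaFixed = stats::setNames(stats::lm.fit(X, y)$coefficients,
                                colnames(X)),
    loglikREML = NA_real_, zIndex = as.integer(zIndex),
    counts = as.integer(counts), Q = diag(length(usedIds)),
    S = rep(0, length(usedIds)), X = X, y = y, individualIds = usedIds)
}

#' Simulate a study to files
#'
#' Simulates family-structured genotypes and a phenotype set (Gaussian or
#' threshold-binary) and writes them as \code{<prefix>_genotypes.tsv},
#' \code{<prefix>_phenotypes.tsv} and \code{<prefix>_truth.json} — enough to
#' rerun [runScan()]. Deterministic for a fixed seed.
#'
#' @param outPrefix output path prefix.
#' @param nFamilies,sibsPerFamily,nUnrelated,nSnps,mafLow,mafHigh passed to
#'   [simulateGenotypes()].
#' @param qtlIndices,qtlEffects,components,design,yearVariance passed to the
#'   phenotype simulator.
#' @param binary simulate a threshold-model binary trait; @param tau its
#'   threshold.
#' @param seed integer seed.
#' @return invisibly, the output paths.
#' @export
runSimulation <- function(outPrefix, nFamilies = 150, sibsPerFamily = 2,
                          nUnrelated = 549, nSnps = 1000,
                          mafLow = 0.01, mafHigh = 0.5,
                          qtlIndices = integer(0), qtlEffects = numeric(0),
                          components = c(1, 1, 1),
                          design = designSpec("balanced", 2),
                          yearVariance = 0, binary = FALSE, tau = 0,
                          seed = 1) {
  gm <- simulateGenotypes(nFamilies, sibsPerFamily, nUnrelated, nSnps,
                          mafLow, mafHigh, seed = seed)
  sim <- if (binary)
    simulateBinary(gm, qtlIndices, qtlEffects, components, design,
                   yearVariance, tau = tau, seed = seed + 1L)
  else
    simulateGaussian(gm, qtlIndices, qtlEffects, components, design,
                     yearVariance, seed = seed + 1L)
  gPath <- paste0(outPrefix, "_genotypes.tsv")
  pPath <- paste0(outPrefix, "_phenotypes.tsv")
  tPath <- paste0(outPrefix, "_truth.json")
  writeDosageTable(gm, gPath)
  writeSimulation(sim, pPath, tPath)
  invisible(c(genotypes = gPath, phenotypes = pPath, truth = tPath))
}

#' Replicate-table harness
#'
#' Drives repeated simulation + scan runs and tabulates per-scenario means
#' and standard deviations of the quantities reported in method-validation
#' tables: estimated QTL effect, average p at the QTL, power at p < 1e-6,
#' the three variance components and the inflation factor. Scenarios are
#' lists with elements \code{label}, \code{qtlEffect} (0 for null),
#' \code{binary}, \code{tau}, and optionally \code{design},
#' \code{components}, \code{nReplicates}.
#'
#' @param gm genotypes to scan; @param grm matching GRM (computed if NULL).
#' @param scenarios non-empty list of scenario lists.
#' @param design default repeat design; @param nReplicates default replicate
#'   count; @param seed base seed (replicate r uses seed + r).
#' @param qtlMinMaf QTLs are drawn among SNPs with MAF at least this.
#' @return data.frame, one row per scenario.
#' @export
replicateTables <- function(gm, grm = NULL, scenarios,
                            design = designSpec("balanced", 4),
                            nReplicates = 20, seed = 1, qtlMinMaf = 0.05) {
  if (!length(scenarios)) stop("empty scenario list")
  if (is.null(grm)) grm <- computeGRM(gm)
  maf <- minorAlleleFreq(gm)
  eligible <- which(maf >= qtlMinMaf)
  rows <- lapply(scenarios, function(sc) {
    des <- sc$design %||% design
    comp <- sc$components %||% c(1, 1, 1)
    nr <- sc$nReplicates %||% nReplicates
    binary <- isTRUE(sc$binary)
    eff <- sc$qtlEffect %||% 0
    fails <- 0L
    recs <- vector("list", nr)
    for (r in seq_len(nr)) {
      recs[[r]] <- tryCatch({
        set.seed(seed + r)
        qtl <- if (eff != 0) sample(eligible, 1L) else integer(0)
        sim <- if (binary)
          simulateBinary(gm, qtl, rep(eff, length(qtl)), comp, des,
                         tau = sc$tau %||% 0, seed = NULL, grm = grm)
        else
          simulateGaussian(gm, qtl, rep(eff, length(qtl)), comp, des,
                           seed = NULL, grm = grm)
        fit <- fitNull(sim$pheno, ~ 1, grm)
        scan <- rglsScan(gm, fit)
        tab <- scanTable(scan)
        probe <- if (length(qtl)) qtl else eligible[1]
        c(beta = unname(tab$beta[probe]), p = unname(tab$p[probe]),
          hit = as.numeric(tab$p[probe] < 1e-6),
          varComp(fit), lambda = lambdaGC(scan))
      }, error = function(e) NULL)
      if (is.null(recs[[r]])) fails <- fails + 1L
    }
    recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(recs)) stop("scenario '", sc$label, "': all replicates failed")
    data.frame(label = sc$label %||% "", qtl_effect = eff, binary = binary,
      beta_mean = mean(recs[, "beta"]), beta_sd = stats::sd(recs[, "beta"]),
      p_mean = mean(recs[, "p"]), power_1e6 = mean(recs[, "hit"]),
      sigma_g2 = mean(recs[, "sigma_g2"]),
      sigma_p2 = mean(recs[, "sigma_p2"]),
      sigma_e2 = mean(recs[, "sigma_e2"]),
      lambda = mean(recs[, "lambda"]),
      n_replicates = nrow(recs), n_failed = fails)
  })
  do.call(rbind, rows)
}
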