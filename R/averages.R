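#' Collapse repeated records to per-individual averages
#'
#' The baseline response for the comparison model: the arithmetic mean trait
#' value per individual. Time-varying covariates (year, age, ...) cannot be
#' carried into an averages analysis and are dropped.
#'
#' @param pheno observation-level data.frame with columns \code{id},
#'   \code{trait}.
#' @return data.frame with one row per individual: \code{id}, \code{trait}
#'   (the mean) and \code{n_obs}.
#' @export
averagePhenotypes <- function(pheno) {
  stopifnot(all(c("id", "trait") %in% names(pheno)))
  agg <- stats::aggregate(pheno$trait, by = list(id = pheno$id),
    FUN = function(v) c(mean(v), length(v)))
  data.frame(id = agg$id, trait = agg$x[, 1], n_obs = as.integer(agg$x[, 2]),
             stringsAsFactors = FALSE)
}

#' Association scan on individual-average phenotypes
#'
#' The comparison method: fits the two-component polygenic model
#' V = G sigma_g2 + I sigma_e2 on the per-individual means (no
#' permanent-environment component — with one record per individual it is not
#' separable), then runs the same whitened generalized least-squares scan.
#' Individuals are weighted equally regardless of how many records went into
#' their mean, mirroring the naive averages practice.
#'
#' @param avgPheno output of [averagePhenotypes()] (one row per individual).
#' @param gm the \linkS4class{GenotypeMatrix}.
#' @param grm the \linkS4class{RelationshipMatrix}.
#' @return an \linkS4class{RglsScan}.
#' @export
scanAverages <- function(avgPheno, gm, grm) {
  if (anyDuplicated(avgPheno$id))
    stop("averages scan needs exactly one record per individual")
  fit <- fitNull(avgPheno, ~ 1, grm, permEnv = FALSE)
  rglsScan(gm, fit)
}

neglog10AtQtl <- function(scan, qtlIndex) {
  p <- scanTable(scan)$p[qtlIndex]
  -log10(pmax(p, .Machine$double.xmin))
}

#' Compare the repeated-measures scan with the averages baseline
#'
#' Simulates Gaussian phenotypes with one QTL under a given scenario, runs
#' both methods per replicate, and summarizes: percent increase in mean
#' -log10 p at the QTL (ratio of replicate means), the correlation of
#' -log10 p across all SNPs, and each method's mean effect estimate and
#' inflation factor. Year effects, when present, are simulated as random
#' yearly draws but fitted as fixed effects in the repeated-measures model
#' only; the averages model cannot represent them.
#'
#' @param gm genotypes; @param grm matching relationship matrix (computed if
#'   NULL).
#' @param design a [designSpec()].
#' @param components variance components for the simulation.
#' @param yearVariance variance of yearly effects.
#' @param qtlEffect additive QTL effect (default 0.5).
#' @param qtlIndex SNP column carrying the QTL (default: middle SNP).
#' @param nReplicates number of simulation replicates.
#' @param seed integer seed; replicate r uses seed + r so that scenarios
#'   sharing a seed share their genetic and residual draws (common random
#'   numbers).
#' @return one-row data.frame with the comparison summary.
#' @export
compareMethods <- function(gm, grm = NULL, design = designSpec("unbalanced"),
                           components = c(1, 1, 1), yearVariance = 0,
                           qtlEffect = 0.5, qtlIndex = NULL,
                           nReplicates = 20, seed = 1) {
  if (is.null(grm)) grm <- computeGRM(gm)
  if (is.null(qtlIndex)) qtlIndex <- max(1L, nSnps(gm) %/% 2L)
  res <- vector("list", nReplicates)
  nFailed <- 0L
  for (r in seq_len(nReplicates)) {
    out <- tryCatch({
      sim <- simulateGaussian(gm, qtlIndices = qtlIndex,
        qtlEffects = qtlEffect, components = components, design = design,
        yearVariance = yearVariance, seed = seed + r, grm = grm)
      fixed <- if (yearVariance > 0) ~ factor(year) else ~ 1
      fitR <- fitNull(sim$pheno, fixed, grm)
      scanR <- rglsScan(gm, fitR)
      avg <- averagePhenotypes(sim$pheno)
      scanA <- scanAverages(avg, gm, grm)
      pR <- scanTable(scanR)$p
      pA <- scanTable(scanA)$p
      ok <- is.finite(pR) & is.finite(pA)
      list(nlR = neglog10AtQtl(scanR, qtlIndex),
           nlA = neglog10AtQtl(scanA, qtlIndex),
           corr = stats::cor(-log10(pR[ok]), -log10(pA[ok])),
           betaR = scanTable(scanR)$beta[qtlIndex],
           betaA = scanTable(scanA)$beta[qtlIndex],
           lamR = lambdaGC(scanR), lamA = lambdaGC(scanA))
    }, error = function(e) NULL)
    if (is.null(out)) nFailed <- nFailed + 1L else res[[r]] <- out
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("all replicates failed")
  take <- function(f) vapply(res, `[[`, numeric(1), f)
  data.frame(
    year_variance = yearVariance,
    pct_increase_neglogp = 100 * (mean(take("nlR")) / mean(take("nlA")) - 1),
    corr_neglogp = mean(take("corr")),
    mean_beta_repeated = mean(take("betaR")),
    mean_beta_averages = mean(take("betaA")),
    mean_lambda_repeated = mean(take("lamR")),
    mean_lambda_averages = mean(take("lamA")),
    mean_neglogp_repeated = mean(take("nlR")),
    mean_neglogp_averages = mean(take("nlA")),
    n_replicates = length(res), n_failed = nFailed)
}

#' Power gain as a function of the year-effect variance share
#'
#' Runs [compareMethods()] at a series of year-variance shares s, setting the
#' year variance to s / (1 - s) times the non-year phenotypic variance
#' (sigma_g2 + sigma_p2 + sigma_e2), and tabulates the percent increase in
#' -log10 p at the QTL. Replicates are matched across shares through common
#' random numbers, so the trend in the share is not masked by between-
#' replicate noise.
#'
#' @inheritParams compareMethods
#' @param shares year-variance shares of total phenotypic variance, in
#'   [0, 1).
#' @return data.frame with one row per share (columns of
#'   [compareMethods()] plus \code{share}).
#' @export
yearEffectSweep <- function(gm, grm = NULL, shares = c(0, 0.07, 0.25, 0.57),
                            design = designSpec("unbalanced"),
                            components = c(1, 1, 1), qtlEffect = 0.5,
                            qtlIndex = NULL, nReplicates = 20, seed = 1) {
  stopifnot(all(shares >= 0 & shares < 1))
  if (is.null(grm)) grm <- computeGRM(gm)
  base <- sum(checkComponents(components))
  rows <- lapply(shares, function(s) {
    yv <- if (s > 0) s / (1 - s) * base else 0
    row <- compareMethods(gm, grm, design, components, yearVariance = yv,
      qtlEffect = qtlEffect, qtlIndex = qtlIndex,
      nReplicates = nReplicates, seed = seed)
    cbind(share = s, row)
  })
  do.call(rbind, rows)
}
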