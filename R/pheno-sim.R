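#' Repeat-design specification
#'
#' Describes how many phenotype records each individual gets. In the balanced
#' design every individual has exactly \code{obsPerIndividual} records. In the
#' unbalanced design counts are drawn Poisson(\code{meanObs}) — the standard
#' count law with mean equal to variance, here 2.0/2.0 by default, so the
#' marginal moments match field designs where recapture is haphazard —
#' and individuals drawing 0 are absent from that replicate. Each record is
#' assigned a study year uniformly at random, without repeating a year within
#' an individual when the count allows.
#'
#' @param mode "balanced" or "unbalanced".
#' @param obsPerIndividual records per individual (balanced mode).
#' @param meanObs Poisson mean (unbalanced mode; default 2).
#' @param nYears number of study years (default 10).
#' @return a list of class \code{designSpec}.
#' @export
designSpec <- function(mode = c("balanced", "unbalanced"),
                       obsPerIndividual = 2, meanObs = 2, nYears = 10) {
  mode <- match.arg(mode)
  stopifnot(obsPerIndividual >= 1, meanObs > 0, nYears >= 1)
  structure(list(mode = mode, obsPerIndividual = obsPerIndividual,
                 meanObs = meanObs, nYears = nYears), class = "designSpec")
}

#' Draw an observation-level design
#'
#' @param individualIds character vector of individual labels.
#' @param design a [designSpec()].
#' @param seed optional integer seed.
#' @return data.frame with columns \code{id} and \code{year} (one row per
#'   phenotype record).
#' @examples
#' makeDesign(c("a", "b"), designSpec("balanced", 2), seed = 1)
#' @export
makeDesign <- function(individualIds, design, seed = NULL) {
  stopifnot(inherits(design, "designSpec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(individualIds)
  counts <- if (design$mode == "balanced") rep(design$obsPerIndividual, n)
            else stats::rpois(n, design$meanObs)
  keep <- counts > 0
  ids <- rep(individualIds[keep], counts[keep])
  years <- unlist(lapply(counts[keep], function(k) {
    if (k <= design$nYears) sample.int(design$nYears, k)
    else sample.int(design$nYears, k, replace = TRUE)
  }), use.names = FALSE)
  data.frame(id = ids, year = years, stringsAsFactors = FALSE)
}

sampleMVN <- function(grm, sd2) {
  # one draw from N(0, sd2 * G) using the cached eigendecomposition
  eg <- grmEigen(grm)
  n <- length(eg$values)
  as.numeric(eg$vectors %*% (sqrt(pmax(eg$values, 0) * sd2) * stats::rnorm(n)))
}

simulateLiability <- function(gm, qtlIndices, qtlEffects, components, design,
                              yearVariance, seed, grm) {
  if (!is.null(seed)) set.seed(seed)
  vc <- checkComponents(components)
  qtlIndices <- as.integer(qtlIndices)
  stopifnot(length(qtlIndices) == length(qtlEffects),
            !anyDuplicated(qtlIndices),
            all(qtlIndices >= 1 & qtlIndices <= nSnps(gm)),
            all(is.finite(qtlEffects)))
  if (is.null(grm)) grm <- computeGRM(gm)
  ids <- individualIds(gm)
  n <- length(ids)

  obs <- makeDesign(ids, design, seed = NULL)
  N <- nrow(obs)
  zi <- match(obs$id, ids)

  g <- if (vc["sigma_g2"] > 0) sampleMVN(grm, vc["sigma_g2"]) else numeric(n)
  p <- stats::rnorm(n, 0, sqrt(vc["sigma_p2"]))
  e <- stats::rnorm(N, 0, sqrt(vc["sigma_e2"]))
  yearEff <- if (yearVariance > 0)
    stats::rnorm(design$nYears, 0, sqrt(yearVariance)) else
    rep(0, design$nYears)

  qtlContrib <- numeric(n)
  if (length(qtlIndices)) {
    d <- dosages(gm)[, qtlIndices, drop = FALSE]
    f <- colMeans(d, na.rm = TRUE) / 2
    for (k in seq_along(qtlIndices)) {
      dk <- d[, k]
      dk[is.na(dk)] <- 2 * f[k]
      qtlContrib <- qtlContrib + dk * qtlEffects[k]
    }
  }

  yu <- qtlContrib[zi] + g[zi] + p[zi] + yearEff[obs$year] + e
  names(g) <- names(p) <- ids
  list(obs = obs, yu = as.numeric(yu), g = g, p = p,
       yearEff = yearEff, vc = vc,
       qtlIndices = qtlIndices, qtlEffects = as.numeric(qtlEffects))
}

#' Simulate a Gaussian repeated-measures phenotype
#'
#' Observation values follow y = sum_qtl x beta + Z g + Z p + year + e with
#' g ~ N(0, sigma_g2 G) (G the VanRaden GRM of the supplied genotypes),
#' p ~ N(0, sigma_p2 I_n), e ~ N(0, sigma_e2 I_N) and i.i.d. year effects
#' N(0, yearVariance) shared by all records of a year. Deterministic for a
#' fixed seed.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param qtlIndices,qtlEffects QTL positions (column indices) and additive
#'   allele-substitution effects; empty by default.
#' @param components variance components (sigma_g2, sigma_p2, sigma_e2);
#'   default c(1, 1, 1).
#' @param design a [designSpec()].
#' @param yearVariance variance of the yearly effects (default 0).
#' @param seed optional integer seed.
#' @param grm optional precomputed \linkS4class{RelationshipMatrix} for the
#'   same genotypes (avoids recomputing it inside replicate loops).
#' @return list with \code{pheno} (data.frame: id, trait, year) and
#'   \code{truth} (a \linkS4class{SimTruth}).
#' @export
simulateGaussian <- function(gm, qtlIndices = integer(0),
                             qtlEffects = numeric(0),
                             components = c(1, 1, 1),
                             design = designSpec("balanced", 2),
                             yearVariance = 0, seed = NULL, grm = NULL) {
  sim <- simulateLiability(gm, qtlIndices, qtlEffects, components, design,
                           yearVariance, seed, grm)
  pheno <- data.frame(id = sim$obs$id, trait = sim$yu, year = sim$obs$year,
                      stringsAsFactors = FALSE)
  truth <- new("SimTruth", g = sim$g, p = sim$p, yearEffects = sim$yearEff,
    liability = sim$yu, tau = NA_real_, qtlIndices = sim$qtlIndices,
    qtlEffects = sim$qtlEffects, components = sim$vc,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  list(pheno = pheno, truth = truth)
}

#' Simulate a binary phenotype under the liability threshold model
#'
#' The underlying liability y_u is a Gaussian trait as in
#' [simulateGaussian()]; the observed record is y = 1 when y_u > tau and 0
#' otherwise. The threshold is expressed relative to the mean liability of
#' common-allele homozygotes, so tau = 0 yields an equal proportion of zeros
#' and ones among carriers of two common alleles regardless of the QTL
#' effect.
#'
#' @inheritParams simulateGaussian
#' @param tau threshold on the liability scale (relative to common-homozygote
#'   mean; default 0).
#' @return list with \code{pheno} (trait is 0/1) and \code{truth} (retains
#'   the liabilities and threshold).
#' @export
simulateBinary <- function(gm, qtlIndices = integer(0),
                           qtlEffects = numeric(0),
                           components = c(1, 1, 1),
                           design = designSpec("balanced", 2),
                           yearVariance = 0, tau = 0, seed = NULL,
                           grm = NULL) {
  sim <- simulateLiability(gm, qtlIndices, qtlEffects, components, design,
                           yearVariance, seed, grm)
  # anchor: mean liability of individuals homozygous for the common allele
  anchor <- 0
  if (length(sim$qtlIndices)) {
    d <- dosages(gm)[, sim$qtlIndices, drop = FALSE]
    f <- colMeans(d, na.rm = TRUE) / 2
    anchor <- sum(ifelse(f > 0.5, 2, 0) * sim$qtlEffects)
  }
  thr <- tau + anchor
  yBin <- as.numeric(sim$yu > thr)
  pheno <- data.frame(id = sim$obs$id, trait = yBin, year = sim$obs$year,
                      stringsAsFactors = FALSE)
  truth <- new("SimTruth", g = sim$g, p = sim$p, yearEffects = sim$yearEff,
    liability = sim$yu, tau = thr, qtlIndices = sim$qtlIndices,
    qtlEffects = sim$qtlEffects, components = sim$vc,
    seed = if (is.null(seed)) NULL else as.integer(seed))
  list(pheno = pheno, truth = truth)
}

#' Write simulated phenotypes and their ground truth
#'
#' Emits the observation table as TSV and a JSON sidecar retaining the seed,
#' variance components, QTL positions/effects and threshold.
#'
#' @param sim a list as returned by [simulateGaussian()]/[simulateBinary()].
#' @param phenoPath,truthPath output paths.
#' @return invisibly, the two paths.
#' @export
writeSimulation <- function(sim, phenoPath, truthPath) {
  utils::write.table(sim$pheno, phenoPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(
    seed = tr@seed, components = as.list(tr@components),
    qtl_indices = tr@qtlIndices, qtl_effects = tr@qtlEffects,
    tau = tr@tau, n_observations = length(tr@liability),
    year_effects = tr@yearEffects),
    truthPath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(phenoPath, truthPath))
}
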