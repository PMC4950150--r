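#' Liability threshold model for a single bi-allelic QTL
#'
#' Holds the parameters of the threshold model that maps an additive effect
#' on the underlying Gaussian liability to the observed 0/1 scale: per-allele
#' liability effect \code{betaU}, threshold \code{tau} (relative to the mean
#' liability of common-allele homozygotes), non-QTL liability variance
#' \code{sigmaU2}, and allele frequency \code{p} (Hardy-Weinberg genotype
#' proportions assumed).
#'
#' @param betaU additive effect per allele on the liability scale.
#' @param tau threshold.
#' @param sigmaU2 non-QTL liability variance (> 0).
#' @param p frequency of the effect allele, in (0, 1); may be NA when it is
#'   to be solved from a population proportion via [solveAlleleFreq()].
#' @return a list of class \code{thresholdModel}.
#' @export
thresholdModel <- function(betaU, tau = 0, sigmaU2 = 3, p = NA_real_) {
  stopifnot(is.finite(betaU), is.finite(tau), sigmaU2 > 0,
            is.na(p) || (p > 0 && p < 1))
  structure(list(betaU = betaU, tau = tau, sigmaU2 = sigmaU2, p = p),
            class = "thresholdModel")
}

#' Penetrance of the threshold model
#'
#' P(y = 1 | genotype g) = Phi((g * betaU - tau) / sqrt(sigmaU2)).
#'
#' @param model a [thresholdModel()].
#' @param g genotype dosage(s) in \{0, 1, 2\}.
#' @return probability (vectorized over \code{g}).
#' @examples
#' penetrance(thresholdModel(1, 0, 3), 0:2)
#' @export
penetrance <- function(model, g) {
  stopifnot(inherits(model, "thresholdModel"), all(g %in% 0:2))
  stats::pnorm((g * model$betaU - model$tau) / sqrt(model$sigmaU2))
}

hweWeights <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

#' Expected slope of a 0/1 trait on genotype dosage
#'
#' The population least-squares regression slope of the observed binary
#' phenotype on the dosage under Hardy-Weinberg genotype frequencies:
#' Cov(E[y|g], g) / Var(g) with g ~ Binomial(2, p). This is what a
#' (generalized) least-squares association scan estimates, in expectation,
#' when the trait was generated by thresholding a Gaussian liability.
#'
#' @param model a [thresholdModel()] with a concrete allele frequency.
#' @return the expected observed-scale effect estimate.
#' @examples
#' m <- thresholdModel(1, 0, 3)
#' m$p <- solveAlleleFreq(m, 0.63)
#' expectedObservedSlope(m)  # ~ 0.201
#' @export
expectedObservedSlope <- function(model) {
  stopifnot(inherits(model, "thresholdModel"), is.finite(model$p))
  w <- hweWeights(model$p)
  g <- 0:2
  pen <- penetrance(model, g)
  eg <- sum(w * g)
  covyg <- sum(w * pen * (g - eg))
  varg <- sum(w * (g - eg)^2)
  covyg / varg
}

#' Population proportion of ones under the threshold model
#'
#' @param model a [thresholdModel()] with a concrete allele frequency.
#' @return P(y = 1) averaged over Hardy-Weinberg genotype frequencies.
#' @export
populationProportion <- function(model) {
  stopifnot(inherits(model, "thresholdModel"), is.finite(model$p))
  sum(hweWeights(model$p) * penetrance(model, 0:2))
}

#' Solve the allele frequency from a population proportion of ones
#'
#' Inverts [populationProportion()]: finds the unique p in (0, 1) for which
#' the Hardy-Weinberg mixture of penetrances equals \code{fraction}. The
#' mixture is monotone in p (for betaU != 0), so bisection to 1e-10 suffices.
#'
#' @param model a [thresholdModel()] (its \code{p} is ignored).
#' @param fraction observed population proportion of ones, strictly between
#'   the penetrances at g = 0 and g = 2.
#' @return the allele frequency p.
#' @export
solveAlleleFreq <- function(model, fraction) {
  stopifnot(inherits(model, "thresholdModel"))
  pen <- penetrance(model, 0:2)
  lo <- min(pen[1], pen[3]); hi <- max(pen[1], pen[3])
  if (fraction <= lo || fraction >= hi)
    stop(sprintf("fraction %.4g outside attainable range (%.4g, %.4g)",
                 fraction, lo, hi))
  f <- function(p) {
    m <- model; m$p <- p
    populationProportion(m) - fraction
  }
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Expected observed-scale genetic variance of a binary trait
#'
#' First-order liability-to-observed transform at the threshold: a polygenic
#' variance sigma_g2 on the liability scale appears on the 0/1 scale as
#' phi(tau / sqrt(sigmaU2))^2 * sigma_g2 / sigmaU2, with phi the standard
#' normal density. At the defaults (sigma_g2 = 1, sigmaU2 = 3, tau = 0) this
#' is phi(0)^2 / 3 = 0.053.
#'
#' @param sigmaG2 liability-scale genetic variance (> 0).
#' @param sigmaU2 total non-QTL liability variance (>= sigmaG2).
#' @param tau threshold (default 0).
#' @return expected observed-scale variance.
#' @examples
#' expectedObservedGeneticVariance(1, 3, 0)  # 0.053
#' @export
expectedObservedGeneticVariance <- function(sigmaG2, sigmaU2, tau = 0) {
  stopifnot(sigmaU2 >= sigmaG2, sigmaG2 >= 0, sigmaU2 > 0)
  stats::dnorm(tau / sqrt(sigmaU2))^2 * sigmaG2 / sigmaU2
}

#' Expected observed-scale estimates for a set of binary proportions
#'
#' For each (threshold, proportion-of-ones) pair, solves the effective allele
#' frequency and evaluates the expected observed-scale slope. Reproduces the
#' expected-estimate column of a threshold-model validation table.
#'
#' @param betaU liability-scale effect per allele.
#' @param taus thresholds.
#' @param fractions population proportions of ones (same length as
#'   \code{taus}).
#' @param sigmaU2 non-QTL liability variance.
#' @return data.frame with columns tau, fraction, allele_freq,
#'   expected_slope.
#' @examples
#' expectedEstimateTable(1, c(0, -1), c(0.63, 0.80))
#' @export
expectedEstimateTable <- function(betaU, taus, fractions, sigmaU2 = 3) {
  stopifnot(length(taus) == length(fractions))
  out <- lapply(seq_along(taus), function(i) {
    m <- thresholdModel(betaU, taus[i], sigmaU2)
    p <- solveAlleleFreq(m, fractions[i])
    m$p <- p
    data.frame(tau = taus[i], fraction = fractions[i], allele_freq = p,
               expected_slope = expectedObservedSlope(m))
  })
  do.call(rbind, out)
}
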