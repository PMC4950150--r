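#' Diagnostic plots for a scan
#'
#' \code{qqPlot} draws observed vs expected -log10 p with the identity line
#' and the inflation factor in the title; \code{manhattanPlot} draws
#' -log10 p along the genome, colouring by chromosome. If \code{path} is
#' given a PNG is written, otherwise the current device is used.
#'
#' @param scan an \linkS4class{RglsScan}.
#' @param path optional PNG path.
#' @param ... passed to \code{plot()}.
#' @return the path (or NULL), invisibly.
#' @export
qqPlot <- function(scan, path = NULL, ...) {
  tab <- scanTable(scan)
  p <- tab$p[!tab$excluded & is.finite(tab$p)]
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  obs <- sort(-log10(p))
  expd <- sort(-log10(stats::ppoints(length(p))))
  graphics::plot(expd, obs, pch = 20, cex = 0.6,
    xlab = expression(Expected ~ -log[10](p)),
    ylab = expression(Observed ~ -log[10](p)),
    main = sprintf("QQ plot (lambda = %.3f)", lambdaGC(scan)), ...)
  graphics::abline(0, 1, col = "red")
  invisible(path)
}

#' @rdname qqPlot
#' @export
manhattanPlot <- function(scan, path = NULL, ...) {
  tab <- as.data.frame(scanTable(scan))
  tab <- tab[!tab$excluded & is.finite(tab$p), ]
  if (!is.null(path)) {
    grDevices::png(path, width = 1000, height = 450)
    on.exit(grDevices::dev.off())
  }
  chrom <- if (all(is.na(tab$chrom))) rep("1", nrow(tab)) else tab$chrom
  chromF <- factor(chrom, levels = unique(chrom))
  col <- c("grey30", "steelblue")[1 + (as.integer(chromF) %% 2)]
  graphics::plot(seq_len(nrow(tab)), -log10(tab$p), col = col, pch = 20,
    cex = 0.6, xlab = "SNP index (by chromosome)",
    ylab = expression(-log[10](p)), main = "Association scan", ...)
  graphics::abline(h = -log10(0.05 / nrow(tab)), col = "red", lty = 2)
  invisible(path)
}
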