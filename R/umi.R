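#' Fit the UMI-to-read-count transform
#'
#' UMI protocols report absolute transcript counts, while the quality
#' features and trained classifiers are defined on read counts. The bridge
#' is a cubic polynomial on the log scale: with a pseudo count added to both
#' sides,
#' \deqn{\log_{10}(y_i + c) = a_0 + a_1 t_i + a_2 t_i^2 + a_3 t_i^3,\quad
#'       t_i = \log_{10}(x_i + c)}
#' where \eqn{x_i} is gene i's mean transcript count and \eqn{y_i} its mean
#' read count in a paired reference dataset. The model is linear in its
#' coefficients, so ordinary least squares gives the exact solution.
#'
#' @param meanTranscripts Per-gene mean transcript counts (x).
#' @param meanReads Per-gene mean read counts (y), same length.
#' @param pseudocount Positive pseudo count added to both sides
#'   (default 0.1).
#' @return List of class \code{"umi_transform"}: coefficients \code{a0..a3},
#'   \code{pseudocount}, residual sum of squares \code{rss}, and
#'   \code{nGenes}.
#' @export
fitUmiTransform <- function(meanTranscripts, meanReads, pseudocount = 0.1) {
    x <- as.numeric(meanTranscripts)
    y <- as.numeric(meanReads)
    if (length(x) != length(y))
        stop("meanTranscripts and meanReads must have the same length")
    if (length(x) < 4) stop("at least 4 genes are required for a cubic fit")
    if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
    if (pseudocount <= 0) stop("'pseudocount' must be positive")
    t <- log10(x + pseudocount)
    z <- log10(y + pseudocount)
    X <- cbind(1, t, t^2, t^3)
    qrX <- qr(X)
    if (qrX$rank < 4)
        stop("rank-deficient design (too few distinct transcript levels)")
    fit <- stats::lm.fit(X, z)
    structure(list(coefficients = setNames(fit$coefficients,
                                           c("a0", "a1", "a2", "a3")),
                   pseudocount = pseudocount,
                   rss = sum(fit$residuals^2), nGenes = length(x)),
              class = "umi_transform")
}

#' @export
print.umi_transform <- function(x, ...) {
    cat(sprintf("UMI transform: log10(y + %g) = %.4g + %.4g t + %.4g t^2 + %.4g t^3 (t = log10(x + %g))\n",
                x$pseudocount, x$coefficients[1], x$coefficients[2],
                x$coefficients[3], x$coefficients[4], x$pseudocount))
    cat(sprintf("  fit on %d genes, RSS = %.4g\n", x$nGenes, x$rss))
    invisible(x)
}

#' Apply the UMI transform to a transcript-count matrix
#'
#' Applies the fitted gene-mean curve entry-wise: every transcript count
#' \eqn{c} maps to \eqn{\max(0, 10^{P(\log_{10}(c + pc))} - pc)} where P is
#' the fitted cubic. Negative back-transformed values are clipped to 0.
#'
#' @param model A \code{"umi_transform"} from [fitUmiTransform()].
#' @param x A \linkS4class{CellCounts} of transcript counts
#'   (unit \code{raw_counts}).
#' @return A \linkS4class{CellCounts} of pseudo-read counts.
#' @export
applyUmiTransform <- function(model, x) {
    stopifnot(inherits(model, "umi_transform"), is(x, "CellCounts"))
    if (countUnit(x) != "raw_counts")
        stop("UMI transform applies to raw transcript counts")
    pc <- model$pseudocount
    a <- model$coefficients
    v <- assay(x, "counts")
    t <- log10(v + pc)
    out <- pmax(10^(a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3) - pc, 0)
    res <- CellCounts(out, erccMask = rowData(x)$ercc, unit = "raw_counts")
    metadata(res)$provenance <- "umi_transformed"
    res
}
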