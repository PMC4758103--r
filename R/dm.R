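#' Distance-to-median (DM) expression noise per gene
#'
#' A mean-independent noise measure: for each gene expressed in the chosen
#' cells, the squared coefficient of variation CV^2 = var/mean^2 is computed
#' across cells, genes are ordered by log10 mean expression, and DM is the
#' deviation of log10(CV^2) from a centered rolling median (window truncated
#' at the edges) along that ordering. By construction the DM values have
#' median near zero and are decoupled from expression level.
#'
#' Genes with zero mean or zero CV^2 over the subset have no defined DM and
#' are excluded from the result.
#'
#' @param nm A \linkS4class{NormalizedCounts} object.
#' @param cells Optional cell identifiers (or index) selecting the subset;
#'   default all cells.
#' @param window Rolling-median window in genes (default 50; must be >= 3).
#' @return Named numeric vector of DM values for the genes with a defined DM.
#' @export
computeDM <- function(nm, cells = NULL, window = 50) {
    stopifnot(is(nm, "NormalizedCounts"))
    if (window < 3) stop("'window' must be at least 3")
    v <- assay(nm, "normalized")[!rowData(nm)$ercc, , drop = FALSE]
    if (!is.null(cells)) v <- v[, cells, drop = FALSE]
    if (ncol(v) < 2) stop("at least 2 cells are required to compute DM")
    mu <- rowMeans(v)
    va <- rowSums((v - mu)^2) / (ncol(v) - 1)
    keep <- mu > 0 & va > 0
    if (sum(keep) < window)
        stop(sprintf("only %d gene(s) with defined CV^2; window is %d",
                     sum(keep), window))
    mu <- mu[keep]
    cv2 <- va[keep] / mu^2
    ord <- order(log10(mu))
    y <- log10(cv2)[ord]
    med <- .rollingMedian(y, window)
    dm <- numeric(length(y))
    dm[ord] <- y - med
    names(dm) <- names(mu)
    dm
}

# centered rolling median, truncated at the edges
.rollingMedian <- function(y, window) {
    n <- length(y)
    hl <- (window - 1) %/% 2
    hr <- window %/% 2
    vapply(seq_len(n), function(i)
        stats::median(y[max(1, i - hl):min(n, i + hr)]), numeric(1))
}
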