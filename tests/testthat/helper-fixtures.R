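suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# 3-gene x 2-cell matrix with one ERCC row
tinyCountMatrix <- function() {
    matrix(c(2, 3, 5,
             4, 6, 10), nrow = 3,
           dimnames = list(c("G1", "G2", "ERCC-00002"), c("cellA", "cellB")))
}

# counts whose normalized values are exactly a prescribed proportion matrix
# (per-cell non-ERCC sums of `v` must be 1); library sizes arbitrary
countsFromProportions <- function(v, lib = NULL) {
    if (is.null(lib)) lib <- seq(1000, 2000, length.out = ncol(v))
    m <- sweep(v, 2, lib, "*")
    CellCounts(m, erccPrefix = "ERCC-")
}

# normalized matrix with constant CV^2 across genes: genes come in pairs
# (mu*(1+a*x_c), mu*(1-a*x_c)) so per-cell sums stay 1 while the cross-cell
# pattern x gives every gene the same squared coefficient of variation;
# pairs listed in `amp` get amplitude a = amp (CV^2 scaled by amp^2)
constantCV2Normalized <- function(nPairs = 10, nCells = 8, amp = NULL) {
    x <- seq(-0.3, 0.3, length.out = nCells)
    x <- x - mean(x)
    mu <- seq(1, 4, length.out = nPairs)
    mu <- mu / (2 * sum(mu))
    if (is.null(amp)) amp <- rep(1, nPairs)
    v <- matrix(0, 2 * nPairs, nCells)
    for (i in seq_len(nPairs)) {
        v[2 * i - 1, ] <- mu[i] * (1 + amp[i] * x)
        v[2 * i, ] <- mu[i] * (1 - amp[i] * x)
    }
    rownames(v) <- sprintf("G%03d", seq_len(2 * nPairs))
    colnames(v) <- sprintf("c%02d", seq_len(nCells))
    normalizeCounts(countsFromProportions(v))
}

# independent oracle: exact hypergeometric enumeration for a 2x2 table
# with fixed margins (rows: outlier yes/no, cols: annotated yes/no)
enumFisherP <- function(tab, alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    a <- tab[1, 1]
    R1 <- sum(tab[1, ]); C1 <- sum(tab[, 1]); N <- sum(tab)
    lo <- max(0, R1 + C1 - N); hi <- min(R1, C1)
    k <- lo:hi
    probs <- dhyper(k, C1, N - C1, R1)
    if (alternative == "greater") sum(probs[k >= a])
    else sum(probs[probs <= dhyper(a, C1, N - C1, R1) * (1 + 1e-7)])
}

# balanced two-cluster feature table that is linearly separable by quality
separableFeatures <- function(nHigh = 40, nLow = 20, nFeatures = 5,
                              gap = 6, seed = 1) {
    withr::with_seed(seed, {
        v <- matrix(rnorm((nHigh + nLow) * nFeatures), nHigh + nLow,
                    nFeatures)
        v[seq_len(nLow) + nHigh, 1:2] <- v[seq_len(nLow) + nHigh, 1:2] + gap
        dimnames(v) <- list(sprintf("cell_%03d", seq_len(nHigh + nLow)),
                            sprintf("f%02d", seq_len(nFeatures)))
        list(features = CellFeatures(v),
             labels = QualityLabels(rownames(v),
                                    rep(c("HIGH", "LOW"), c(nHigh, nLow))))
    })
}

# small consistent alignment-stats data.frame
statsTable <- function(cells, total = 100, mapped = 90, multimapped = 5,
                       unmapped = 10, exonic = 70, non_exonic = 20,
                       duplicated = 30, ercc_reads = 7) {
    data.frame(cell_id = cells, total_reads = total, mapped = mapped,
               multimapped = multimapped, unmapped = unmapped,
               exonic = exonic, non_exonic = non_exonic,
               duplicated = duplicated, ercc_reads = ercc_reads,
               stringsAsFactors = FALSE)
}

smallSim <- function(seed = 1, ...) {
    simulateDataset(simParams(nHigh = 40, nBroken = 6, nEmpty = 2,
                              nMultiple = 2, nGenes = 600, nErcc = 20,
                              libMean = 20000, seed = seed, ...))
}
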