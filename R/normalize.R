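#' Normalize a count matrix to per-cell read proportions
#'
#' Divides each gene's value by the cell's total over non-ERCC genes, so that
#' every cell becomes a vector of read proportions summing to 1 over
#' endogenous genes. ERCC spike-in rows are carried through divided by the
#' same denominator. This per-cell normalization deliberately avoids any
#' cross-cell reference (such as size-factor normalization), so a cell can be
#' scored without knowledge of the training set. TPM input is treated the
#' same way (each cell's TPMs divided by its non-ERCC TPM total), which keeps
#' the per-cell proportion contract identical across units; provenance is
#' recorded.
#'
#' Cells with zero non-ERCC signal are set to all-zero and flagged in
#' \code{colData(x)$zero_total}.
#'
#' @param x A \linkS4class{CellCounts} object.
#' @return A \linkS4class{NormalizedCounts} object.
#' @export
#' @examples
#' m <- matrix(c(2, 3, 5, 10), 4, 1,
#'             dimnames = list(c("G1", "G2", "G3", "ERCC-1"), "c1"))
#' nm <- normalizeCounts(CellCounts(m))
#' SummarizedExperiment::assay(nm, "normalized")[, 1]
normalizeCounts <- function(x) {
    stopifnot(is(x, "CellCounts"))
    v <- assay(x, "counts")
    if (any(v < 0)) stop("negative values in count matrix")
    ercc <- rowData(x)$ercc
    denom <- colSums(v[!ercc, , drop = FALSE])
    zero <- denom == 0
    if (any(zero))
        warning(sprintf("%d cell(s) with zero non-ERCC total set to 0: %s",
                        sum(zero),
                        paste(utils::head(colnames(v)[zero], 5), collapse = ", ")))
    denom[zero] <- 1
    nv <- sweep(v, 2, denom, "/")
    nv[, zero] <- 0
    se <- SummarizedExperiment(
        assays = list(normalized = nv),
        rowData = DataFrame(ercc = ercc),
        colData = DataFrame(zero_total = zero, row.names = colnames(v)))
    metadata(se)$provenance <-
        if (countUnit(x) == "tpm") "from_tpm" else "from_counts"
    new("NormalizedCounts", se)
}
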