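#' Read a per-cell alignment statistics table
#'
#' Expects a TSV with header containing \code{cell_id} plus the eight
#' accounting columns \code{total_reads, mapped, multimapped, unmapped,
#' exonic, non_exonic, duplicated, ercc_reads}. The read-accounting
#' invariants are validated and violations reported per cell.
#'
#' @param path Path to the TSV file.
#' @return An \linkS4class{AlignmentStats} object (possibly with 0 cells).
#' @export
readAlignmentStats <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("cell_id", .STAT_COLS)
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("missing column(s) in %s: %s", path,
                     paste(miss, collapse = ", ")))
    AlignmentStats(df)
}

#' Write a per-cell alignment statistics table
#'
#' @param st An \linkS4class{AlignmentStats} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAlignmentStats <- function(st, path) {
    df <- data.frame(cell_id = cellIds(st), alignStats(st),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
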