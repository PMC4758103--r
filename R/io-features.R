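#' Read / write a feature table
#'
#' The feature table is stored as a TSV with cells in rows (first column
#' \code{cell_id}, header of feature names) plus a sidecar metadata TSV at
#' \code{<path>.meta} recording each feature's kind and common-set flag.
#'
#' @param ft A \linkS4class{CellFeatures} object.
#' @param path Path to the feature TSV; the sidecar is \code{<path>.meta}.
#' @return \code{writeFeatures} invisibly returns \code{path};
#'   \code{readFeatures} returns a \linkS4class{CellFeatures}.
#' @export
writeFeatures <- function(ft, path) {
    v <- featureMatrix(ft)
    df <- data.frame(cell_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- data.frame(feature = colnames(v), kind = featureKind(ft),
                       common = isCommon(ft), stringsAsFactors = FALSE)
    utils::write.table(meta, paste0(path, ".meta"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    v <- as.matrix(df[, -1, drop = FALSE])
    rownames(v) <- as.character(df[[1]])
    metaPath <- paste0(path, ".meta")
    if (file.exists(metaPath)) {
        meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
        idx <- match(colnames(v), meta$feature)
        if (anyNA(idx))
            stop(sprintf("feature metadata in %s does not cover: %s", metaPath,
                         paste(colnames(v)[is.na(idx)], collapse = ", ")))
        CellFeatures(v, kind = meta$kind[idx], common = meta$common[idx])
    } else {
        CellFeatures(v, kind = "technical",
                     common = colnames(v) %in% commonFeatureNames())
    }
}
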