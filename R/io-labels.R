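#' Read per-cell quality labels
#'
#' TSV with header \code{cell_id}, \code{quality} (HIGH/LOW,
#' case-insensitive) and optional \code{subtype}
#' (broken/empty/multiple/deceptive/none). Unknown label tokens are a parse
#' error.
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{QualityLabels} object.
#' @export
readQualityLabels <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!all(c("cell_id", "quality") %in% colnames(df)))
        stop(sprintf("%s must have 'cell_id' and 'quality' columns", path))
    QualityLabels(df$cell_id, df$quality,
                  if ("subtype" %in% colnames(df)) df$subtype else NULL)
}

#' Write per-cell quality labels
#'
#' @param labels A \linkS4class{QualityLabels} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeQualityLabels <- function(labels, path) {
    df <- data.frame(cell_id = cellIds(labels),
                     quality = as.character(quality(labels)),
                     subtype = as.character(subtype(labels)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write ensemble predictions
#'
#' Emits one row per cell with the predicted quality and the fraction of
#' ensemble members that voted LOW.
#'
#' @param labels A \linkS4class{QualityLabels} of predictions.
#' @param voteFraction Named numeric LOW-vote fractions, one per cell.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePredictions <- function(labels, voteFraction, path) {
    stopifnot(length(voteFraction) == length(labels))
    df <- data.frame(cell_id = cellIds(labels),
                     quality = as.character(quality(labels)),
                     low_vote_fraction = as.numeric(voteFraction[cellIds(labels)]),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read ensemble predictions written by [writePredictions()]
#'
#' @param path Path to the predictions TSV.
#' @return List with elements \code{labels} (\linkS4class{QualityLabels}) and
#'   \code{voteFraction} (named numeric).
#' @export
readPredictions <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    list(labels = QualityLabels(df$cell_id, df$quality),
         voteFraction = setNames(df$low_vote_fraction, df$cell_id))
}
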