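#' Read a gene x cell count matrix
#'
#' Reads a dense TSV/CSV matrix (first column gene identifiers, header row of
#' cell identifiers) or a MatrixMarket triplet file with sibling
#' \code{<stem>.genes.txt} / \code{<stem>.cells.txt} single-column name files.
#'
#' @param path Path to the matrix file.
#' @param format One of \code{"tsv"}, \code{"csv"}, \code{"mtx"}. Guessed from
#'   the file extension when omitted.
#' @param erccPrefix ERCC spike-in rows are recognized by this gene-id prefix.
#' @param unit \code{"raw_counts"} (default) or \code{"tpm"}.
#' @return A \linkS4class{CellCounts} object.
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, format = c("guess", "tsv", "csv", "mtx"),
                            erccPrefix = "ERCC-",
                            unit = c("raw_counts", "tpm")) {
    format <- match.arg(format)
    unit <- match.arg(unit)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    if (format == "guess")
        format <- switch(tolower(tools::file_ext(path)),
                         csv = "csv", mtx = "mtx", "tsv")
    if (format == "mtx") {
        stem <- sub("\\.mtx$", "", path)
        gfile <- paste0(stem, ".genes.txt")
        cfile <- paste0(stem, ".cells.txt")
        if (!file.exists(gfile) || !file.exists(cfile))
            stop(sprintf("sibling name files required: %s, %s", gfile, cfile))
        m <- as.matrix(Matrix::readMM(path))
        genes <- readLines(gfile)
        cells <- readLines(cfile)
        if (length(genes) != nrow(m) || length(cells) != ncol(m))
            stop("name files do not match matrix dimensions")
        dimnames(m) <- list(genes, cells)
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- tryCatch(
            utils::read.table(path, header = TRUE, sep = sep,
                              check.names = FALSE, quote = "",
                              comment.char = "", stringsAsFactors = FALSE),
            error = function(e) stop(sprintf("parse error in %s: %s",
                                             path, conditionMessage(e))))
        genes <- as.character(df[[1]])
        m <- as.matrix(df[, -1, drop = FALSE])
        if (!is.numeric(m)) {
            bad <- which(apply(df[, -1, drop = FALSE], 1,
                               function(r) anyNA(suppressWarnings(as.numeric(r)))))
            stop(sprintf("parse error in %s: non-numeric value at data line %s",
                         path, paste(utils::head(bad, 3), collapse = ", ")))
        }
        rownames(m) <- genes
    }
    if (anyDuplicated(rownames(m)))
        stop(sprintf("duplicated gene identifiers: %s",
                     paste(unique(rownames(m)[duplicated(rownames(m))]),
                           collapse = ", ")))
    if (anyNA(m)) stop("count matrix contains missing values")
    if (any(m < 0)) stop("count matrix contains negative values")
    CellCounts(m, erccPrefix = erccPrefix, unit = unit)
}

#' Write a count matrix
#'
#' Inverse of [readCountMatrix()]: dense TSV/CSV with a \code{gene_id} first
#' column, or MatrixMarket MTX plus the two sibling name files.
#'
#' @param x A \linkS4class{CellCounts} object.
#' @param path Output path.
#' @param format \code{"tsv"}, \code{"csv"} or \code{"mtx"}.
#' @return Invisibly, \code{path}.
#' @export
writeCountMatrix <- function(x, path, format = c("tsv", "csv", "mtx")) {
    format <- match.arg(format)
    m <- assay(x, "counts")
    if (format == "mtx") {
        stem <- sub("\\.mtx$", "", path)
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
        writeLines(rownames(m), paste0(stem, ".genes.txt"))
        writeLines(colnames(m), paste0(stem, ".cells.txt"))
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
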