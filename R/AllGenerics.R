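#' @include AllClasses.R
NULL

#' Accessors for cellqc classes
#'
#' Small accessor generics: \code{erccMask} and \code{countUnit} on
#' \linkS4class{CellCounts} / \linkS4class{NormalizedCounts}, \code{geneSets}
#' on \linkS4class{GeneSetList}, \code{alignStats} on
#' \linkS4class{AlignmentStats}, \code{cellIds}/\code{quality}/\code{subtype}
#' on \linkS4class{QualityLabels}, and
#' \code{featureMatrix}/\code{featureKind}/\code{isCommon} on
#' \linkS4class{CellFeatures}.
#'
#' @param x An object of the relevant class.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("erccMask", function(x) standardGeneric("erccMask"))
#' @rdname accessors
#' @export
setGeneric("countUnit", function(x) standardGeneric("countUnit"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("alignStats", function(x) standardGeneric("alignStats"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("quality", function(x) standardGeneric("quality"))
#' @rdname accessors
#' @export
setGeneric("subtype", function(x) standardGeneric("subtype"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
#' @rdname accessors
#' @export
setGeneric("isCommon", function(x) standardGeneric("isCommon"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("erccMask", "SummarizedExperiment",
          function(x) setNames(rowData(x)$ercc, rownames(x)))
#' @rdname accessors
#' @export
setMethod("countUnit", "CellCounts", function(x) metadata(x)$unit)
#' @rdname accessors
#' @export
setMethod("provenance", "NormalizedCounts", function(x) metadata(x)$provenance)

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

#' @rdname accessors
#' @export
setMethod("alignStats", "AlignmentStats", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("cellIds", "AlignmentStats", function(x) rownames(x@stats))

#' @rdname accessors
#' @export
setMethod("cellIds", "QualityLabels", function(x) x@cell)
#' @rdname accessors
#' @export
setMethod("quality", "QualityLabels", function(x) setNames(x@quality, x@cell))
#' @rdname accessors
#' @export
setMethod("subtype", "QualityLabels", function(x) setNames(x@subtype, x@cell))
#' @export
setMethod("length", "QualityLabels", function(x) length(x@cell))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "CellFeatures", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureKind", "CellFeatures",
          function(x) setNames(x@kind, colnames(x@values)))
#' @rdname accessors
#' @export
setMethod("isCommon", "CellFeatures",
          function(x) setNames(x@common, colnames(x@values)))
#' @rdname accessors
#' @export
setMethod("cellIds", "CellFeatures", function(x) rownames(x@values))

#' Subset a CellFeatures table
#'
#' @param x A \linkS4class{CellFeatures} object.
#' @param i Cell (row) index.
#' @param j Feature (column) index or names.
#' @param drop Ignored; subsetting always returns a CellFeatures object.
#' @param ... Ignored.
#' @export
setMethod("[", "CellFeatures", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@values))
    if (missing(j)) j <- seq_len(ncol(x@values))
    jj <- if (is.character(j)) match(j, colnames(x@values)) else
          seq_len(ncol(x@values))[j]
    if (anyNA(jj)) stop("unknown feature name(s) in subset")
    new("CellFeatures", values = x@values[i, jj, drop = FALSE],
        kind = x@kind[jj], common = x@common[jj])
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "GeneSetList", function(object) {
    cat(sprintf("GeneSetList with %d set(s)\n", length(object@sets)))
    n <- min(length(object@sets), 6L)
    for (i in seq_len(n))
        cat(sprintf("  %s (%d genes)\n", names(object@sets)[i],
                    length(object@sets[[i]])))
    if (length(object@sets) > n) cat("  ...\n")
})

setMethod("show", "AlignmentStats", function(object) {
    cat(sprintf("AlignmentStats for %d cell(s)\n", nrow(object@stats)))
    if (nrow(object@stats))
        print(utils::head(object@stats, 4))
})

setMethod("show", "QualityLabels", function(object) {
    cat(sprintf("QualityLabels for %d cell(s): %d HIGH, %d LOW\n",
                length(object@cell), sum(object@quality == "HIGH"),
                sum(object@quality == "LOW")))
    st <- table(object@subtype)
    st <- st[st > 0 & names(st) != "none"]
    if (length(st))
        cat("  subtypes:", paste(sprintf("%s=%d", names(st), st),
                                 collapse = ", "), "\n")
})

setMethod("show", "CellFeatures", function(object) {
    cat(sprintf("CellFeatures: %d cell(s) x %d feature(s) (%d biological, %d technical, %d common)\n",
                nrow(object@values), ncol(object@values),
                sum(object@kind == "biological"),
                sum(object@kind == "technical"), sum(object@common)))
    cat("  features:", paste(utils::head(colnames(object@values), 8),
                             collapse = ", "),
        if (ncol(object@values) > 8) "..." else "", "\n")
})

setMethod("show", "SVMEnsemble", function(object) {
    cat(sprintf("SVMEnsemble: %d radial-kernel member(s), %d feature(s), beta = %g, seed = %d\n",
                length(object@members), length(object@featureNames),
                object@beta, object@seed))
    cat("  training labels:",
        paste(sprintf("%s=%d", names(object@labelCounts), object@labelCounts),
              collapse = ", "), "\n")
})
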