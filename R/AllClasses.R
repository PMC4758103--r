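#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.COUNT_UNITS <- c("raw_counts", "tpm")
.QUALITY_LEVELS <- c("HIGH", "LOW")
.SUBTYPE_LEVELS <- c("none", "broken", "empty", "multiple", "deceptive")

#' The seven cell-type-independent quality features
#'
#' Names of the default "common" feature set: the features that survive the
#' principal-component loading-quartile filter across cell types and
#' protocols — the cytoplasm read proportion, the mitochondrially localized
#' and mitochondrially encoded gene-set proportions, the mapped, multi-mapped
#' and non-exonic read proportions, and the transcriptome variance.
#'
#' @return Character vector of the seven canonical feature names.
#' @export
#' @examples
#' commonFeatureNames()
commonFeatureNames <- function() {
    c("go_cytoplasm", "mito_localized", "mtDNA_encoded",
      "prop_mapped", "prop_multimapped", "prop_non_exonic",
      "transcriptome_variance")
}

# ---- CellCounts -------------------------------------------------------------

#' CellCounts: a gene x cell expression matrix with spike-in annotation
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay
#' \code{"counts"} holds non-negative expression values (raw read counts or
#' TPM); \code{rowData(x)$ercc} marks ERCC spike-in rows and
#' \code{metadata(x)$unit} records the unit.
#'
#' @slot \dots inherited from SummarizedExperiment.
#' @export
setClass("CellCounts", contains = "SummarizedExperiment")

setValidity("CellCounts", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is missing")
    v <- assay(object, "counts")
    if (anyNA(v)) msg <- c(msg, "counts contain missing values")
    if (!anyNA(v) && any(v < 0)) msg <- c(msg, "counts contain negative values")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and cell identifiers are required as dimnames")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicated gene identifiers: %s",
                 paste(unique(rownames(object)[duplicated(rownames(object))]),
                       collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, sprintf("duplicated cell identifiers: %s",
                 paste(unique(colnames(object)[duplicated(colnames(object))]),
                       collapse = ", ")))
    if (!"ercc" %in% colnames(rowData(object)) ||
        !is.logical(rowData(object)$ercc) ||
        anyNA(rowData(object)$ercc))
        msg <- c(msg, "rowData must carry a complete logical 'ercc' column")
    unit <- metadata(object)$unit
    if (is.null(unit) || !unit %in% .COUNT_UNITS)
        msg <- c(msg, "metadata 'unit' must be 'raw_counts' or 'tpm'")
    if (length(msg)) msg else TRUE
})

#' Construct a CellCounts object
#'
#' @param counts Numeric matrix, genes in rows, cells in columns, with unique
#'   row and column names.
#' @param erccPrefix Gene identifiers starting with this prefix are flagged as
#'   ERCC spike-in rows (ignored when \code{erccMask} is given).
#' @param unit \code{"raw_counts"} or \code{"tpm"}.
#' @param erccMask Optional logical vector, one entry per gene, overriding the
#'   prefix rule.
#' @return A \linkS4class{CellCounts} object.
#' @export
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2,
#'             dimnames = list(c("G1", "G2", "ERCC-1"), c("c1", "c2")))
#' cc <- CellCounts(m)
#' erccMask(cc)
CellCounts <- function(counts, erccPrefix = "ERCC-",
                       unit = c("raw_counts", "tpm"), erccMask = NULL) {
    unit <- match.arg(unit)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(erccMask)) {
        if (!nzchar(erccPrefix))
            stop("'erccPrefix' must be a non-empty string")
        erccMask <- startsWith(rownames(counts) %||% character(), erccPrefix)
    }
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(ercc = as.logical(erccMask)))
    metadata(se)$unit <- unit
    new("CellCounts", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- NormalizedCounts -------------------------------------------------------

#' NormalizedCounts: per-cell proportion-normalized expression
#'
#' Extends \linkS4class{SummarizedExperiment}. The assay \code{"normalized"}
#' holds each gene's share of its cell's total over non-ERCC genes (ERCC rows
#' are carried through divided by the same denominator), so each cell's
#' non-ERCC values sum to 1 unless the cell had no non-ERCC signal
#' (\code{colData(x)$zero_total}).
#'
#' @export
setClass("NormalizedCounts", contains = "SummarizedExperiment")

setValidity("NormalizedCounts", function(object) {
    msg <- character()
    if (!"normalized" %in% assayNames(object))
        return("assay 'normalized' is missing")
    if (!"ercc" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must carry an 'ercc' column")
    if (!"zero_total" %in% colnames(colData(object)))
        msg <- c(msg, "colData must carry a 'zero_total' flag")
    prov <- metadata(object)$provenance
    if (is.null(prov) || !prov %in% c("from_counts", "from_tpm"))
        msg <- c(msg, "metadata 'provenance' must be 'from_counts' or 'from_tpm'")
    v <- assay(object, "normalized")
    ok <- !as.logical(colData(object)$zero_total)
    if (ncol(v) && any(ok)) {
        s <- colSums(v[!rowData(object)$ercc, ok, drop = FALSE])
        if (any(abs(s - 1) > 1e-9))
            msg <- c(msg, "non-ERCC proportions of an unflagged cell do not sum to 1")
    }
    if (length(msg)) msg else TRUE
})

# ---- GeneSetList ------------------------------------------------------------

#' GeneSetList: a named collection of gene sets
#'
#' A thin S4 container for gene sets read from GMT files or built in code.
#' Sets may overlap; each is scored independently when used as a biological
#' feature.
#'
#' @slot sets Named list of character vectors of gene identifiers.
#' @export
setClass("GeneSetList", representation(sets = "list"))

setValidity("GeneSetList", function(object) {
    msg <- character()
    s <- object@sets
    if (length(s) && (is.null(names(s)) || any(!nzchar(names(s)))))
        msg <- c(msg, "every gene set must be named")
    if (anyDuplicated(names(s)))
        msg <- c(msg, sprintf("duplicated set names: %s",
                 paste(unique(names(s)[duplicated(names(s))]), collapse = ", ")))
    if (!all(vapply(s, is.character, logical(1))))
        msg <- c(msg, "gene sets must be character vectors")
    if (any(lengths(s) == 0))
        msg <- c(msg, "empty gene sets are not allowed")
    if (length(msg)) msg else TRUE
})

#' @param sets Named list of character vectors.
#' @rdname GeneSetList-class
#' @export
#' @examples
#' gs <- GeneSetList(list(go_cytoplasm = c("G1", "G2"), mtDNA_encoded = "G3"))
#' names(gs); lengths(geneSets(gs))
GeneSetList <- function(sets) {
    sets <- lapply(sets, function(x) unique(as.character(x)))
    new("GeneSetList", sets = sets)
}

# ---- AlignmentStats ---------------------------------------------------------

.STAT_COLS <- c("total_reads", "mapped", "multimapped", "unmapped",
                "exonic", "non_exonic", "duplicated", "ercc_reads")

#' AlignmentStats: per-cell read accounting
#'
#' Stores, for each cell, the total, mapped, multi-mapped, unaligned, exonic,
#' non-exonic, duplicated, and ERCC read counts produced by the upstream
#' alignment pipeline. Validity enforces the accounting identities
#' \code{mapped + unmapped <= total_reads}, \code{exonic + non_exonic <=
#' mapped}, \code{duplicated <= mapped} and \code{ercc_reads <= mapped}.
#'
#' @slot stats data.frame with one row per cell (cell ids as row names) and
#'   the eight accounting columns.
#' @export
setClass("AlignmentStats", representation(stats = "data.frame"))

setValidity("AlignmentStats", function(object) {
    s <- object@stats
    msg <- character()
    miss <- setdiff(.STAT_COLS, colnames(s))
    if (length(miss))
        return(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
    if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
        msg <- c(msg, "unique cell identifiers are required as row names")
    for (cl in .STAT_COLS) {
        if (anyNA(s[[cl]]) || any(s[[cl]] < 0))
            msg <- c(msg, sprintf("column '%s' must be complete and non-negative", cl))
    }
    bad <- function(cond, what) {
        idx <- which(cond)
        if (length(idx))
            sprintf("%s violated for cell(s): %s", what,
                    paste(rownames(s)[idx], collapse = ", "))
        else character()
    }
    if (nrow(s) && !length(msg)) {
        msg <- c(msg,
            bad(s$mapped + s$unmapped > s$total_reads,
                "mapped + unmapped <= total_reads"),
            bad(s$exonic + s$non_exonic > s$mapped,
                "exonic + non_exonic <= mapped"),
            bad(s$duplicated > s$mapped, "duplicated <= mapped"),
            bad(s$ercc_reads > s$mapped, "ercc_reads <= mapped"))
    }
    if (length(msg)) msg else TRUE
})

#' @param stats data.frame (or coercible) with a \code{cell_id} column or cell
#'   ids as row names, plus the eight accounting columns.
#' @rdname AlignmentStats-class
#' @export
AlignmentStats <- function(stats) {
    stats <- as.data.frame(stats)
    if ("cell_id" %in% colnames(stats)) {
        rownames(stats) <- as.character(stats$cell_id)
        stats$cell_id <- NULL
    }
    new("AlignmentStats", stats = stats[, .STAT_COLS, drop = FALSE])
}

# ---- QualityLabels ----------------------------------------------------------

#' QualityLabels: per-cell HIGH/LOW annotation
#'
#' LOW is the positive class throughout the package (a true positive is a
#' correctly identified low-quality cell). The optional subtype records the
#' microscopy annotation: broken, empty capture site, multiple cells, or
#' deceptive (visually intact but transcriptionally damaged).
#'
#' @slot cell Character vector of cell identifiers.
#' @slot quality Factor with levels HIGH, LOW.
#' @slot subtype Factor with levels none, broken, empty, multiple, deceptive.
#' @export
setClass("QualityLabels",
         representation(cell = "character", quality = "factor",
                        subtype = "factor"))

setValidity("QualityLabels", function(object) {
    msg <- character()
    n <- length(object@cell)
    if (anyDuplicated(object@cell))
        msg <- c(msg, "duplicated cell identifiers")
    if (length(object@quality) != n || length(object@subtype) != n)
        msg <- c(msg, "quality and subtype must match the number of cells")
    if (!identical(levels(object@quality), .QUALITY_LEVELS))
        msg <- c(msg, "quality levels must be HIGH, LOW")
    if (!identical(levels(object@subtype), .SUBTYPE_LEVELS))
        msg <- c(msg, "subtype levels must be none, broken, empty, multiple, deceptive")
    if (anyNA(object@quality)) msg <- c(msg, "quality contains missing values")
    if (length(msg)) msg else TRUE
})

#' @param cell Character vector of cell identifiers.
#' @param quality Character/factor of "HIGH"/"LOW" (case-insensitive).
#' @param subtype Optional character/factor of subtypes; defaults to "none".
#' @rdname QualityLabels-class
#' @export
#' @examples
#' ql <- QualityLabels(c("c1", "c2"), c("high", "LOW"), c(NA, "broken"))
#' table(quality(ql))
QualityLabels <- function(cell, quality, subtype = NULL) {
    cell <- as.character(cell)
    q <- toupper(as.character(quality))
    bad <- !q %in% .QUALITY_LEVELS & !is.na(q)
    if (any(bad))
        stop(sprintf("unknown quality label(s): %s",
                     paste(unique(q[bad]), collapse = ", ")))
    if (is.null(subtype)) subtype <- rep("none", length(cell))
    st <- tolower(as.character(subtype))
    st[is.na(st) | !nzchar(st)] <- "none"
    badst <- !st %in% .SUBTYPE_LEVELS
    if (any(badst))
        stop(sprintf("unknown subtype(s): %s",
                     paste(unique(st[badst]), collapse = ", ")))
    new("QualityLabels", cell = cell,
        quality = factor(q, levels = .QUALITY_LEVELS),
        subtype = factor(st, levels = .SUBTYPE_LEVELS))
}

# ---- CellFeatures -----------------------------------------------------------

#' CellFeatures: the cell x feature table
#'
#' Numeric matrix with cells in rows and features in columns, plus per-feature
#' metadata: whether the feature is biological (a gene-set read proportion) or
#' technical (read accounting / expression shape), and whether it belongs to
#' the cell-type-independent common set.
#'
#' @slot values Numeric matrix, cells x features.
#' @slot kind Character per feature: "biological" or "technical".
#' @slot common Logical per feature.
#' @export
setClass("CellFeatures",
         representation(values = "matrix", kind = "character",
                        common = "logical"))

setValidity("CellFeatures", function(object) {
    msg <- character()
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "cell and feature names are required as dimnames")
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicated feature names")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicated cell names")
    if (anyNA(v)) msg <- c(msg, "feature values contain missing entries")
    if (length(object@kind) != ncol(v) || length(object@common) != ncol(v))
        msg <- c(msg, "kind and common must have one entry per feature")
    if (!all(object@kind %in% c("biological", "technical")))
        msg <- c(msg, "kind must be 'biological' or 'technical'")
    if (length(msg)) msg else TRUE
})

#' @param values Numeric matrix, cells in rows, features in columns.
#' @param kind Character vector (recycled) of "biological"/"technical".
#' @param common Logical vector (recycled) of common-set flags.
#' @rdname CellFeatures-class
#' @export
CellFeatures <- function(values, kind = "technical", common = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    kind <- rep_len(kind, ncol(values))
    common <- rep_len(common, ncol(values))
    new("CellFeatures", values = values, kind = kind, common = common)
}

# ---- SVMEnsemble ------------------------------------------------------------

#' SVMEnsemble: a majority-vote ensemble of radial-kernel SVMs
#'
#' Holds the fitted member SVMs with their selected hyperparameters, the
#' feature names and centering/scaling parameters fitted on the training
#' table, and the training metadata (seed, class counts, selection beta).
#' Predictions are made by majority vote over the members; an exact tie is
#' called LOW (quality control errs toward discarding).
#'
#' @slot members List of \code{list(fit = <e1071 svm>, params = <list>)}.
#' @slot featureNames Ordered feature names the members were trained on.
#' @slot center,scale Named numeric scaling parameters.
#' @slot beta F-beta weight used for hyperparameter selection.
#' @slot seed Master seed of the training run.
#' @slot labelCounts Named integer class counts of the training labels.
#' @slot version Serialization schema tag.
#' @export
setClass("SVMEnsemble",
         representation(members = "list", featureNames = "character",
                        center = "numeric", scale = "numeric",
                        beta = "numeric", seed = "integer",
                        labelCounts = "integer", version = "character"))

setValidity("SVMEnsemble", function(object) {
    msg <- character()
    if (!length(object@members)) msg <- c(msg, "ensemble has no members")
    if (length(object@center) != length(object@featureNames) ||
        length(object@scale) != length(object@featureNames))
        msg <- c(msg, "scaling parameters must match featureNames")
    if (length(msg)) msg else TRUE
})
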