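#' Biological features: gene-set read proportions
#'
#' One feature per gene set: the sum of the cell's normalized values
#' (read proportions) over the set's member genes — the proportion of the
#' cell's endogenous reads mapping to that functional category. Overlaps
#' between sets are ignored: each set is scored independently.
#'
#' @param nm A \linkS4class{NormalizedCounts} object.
#' @param gs A \linkS4class{GeneSetList}; feature names are the set names.
#' @return A \linkS4class{CellFeatures} with one biological feature per set.
#' @export
biologicalFeatures <- function(nm, gs) {
    stopifnot(is(nm, "NormalizedCounts"), is(gs, "GeneSetList"))
    sets <- geneSets(gs)
    if (!length(sets)) stop("empty gene-set collection")
    v <- assay(nm, "normalized")
    genes <- rownames(v)[!rowData(nm)$ercc]
    vals <- matrix(0, ncol(v), length(sets),
                   dimnames = list(colnames(v), names(sets)))
    for (i in seq_along(sets)) {
        members <- intersect(sets[[i]], genes)
        if (!length(members)) {
            warning(sprintf("gene set '%s' has no genes in the matrix; feature set to 0",
                            names(sets)[i]))
            next
        }
        vals[, i] <- colSums(v[members, , drop = FALSE])
    }
    CellFeatures(vals, kind = "biological", common = FALSE)
}

#' Technical features: read accounting and expression shape
#'
#' Per cell: the proportions of mapped, multi-mapped and unaligned reads (of
#' total), of non-exonic and duplicated reads (of mapped), the ERCC-to-exonic
#' read ratio, the total read count, the number of detected (non-ERCC) genes,
#' the transcriptome variance (variance across genes of
#' \code{log10(normalized + 1e-6)}), the Spearman correlation of the cell's
#' normalized expression with the across-cell mean profile, the number of
#' detected genes belonging to the dataset-level highly-expressed/
#' highly-variable set (mean above the across-gene median and DM > 0), and
#' five expression-bin counts (genes whose CPM-scaled normalized value falls
#' in the decades (0,1], (1,10], (10,100], (100,1000], >1000).
#'
#' Zero denominators (e.g. \code{mapped = 0}) yield an imputed 0 with a
#' warning. Cell identifiers of the matrix and the statistics table must
#' match exactly.
#'
#' @param x A \linkS4class{CellCounts} object.
#' @param st An \linkS4class{AlignmentStats} for the same cells.
#' @param window Rolling-median window for the DM component (default 50).
#' @param binBreaks Lower bin edges on the CPM scale (default decades).
#' @return A \linkS4class{CellFeatures} with 16 technical features.
#' @export
technicalFeatures <- function(x, st, window = 50,
                              binBreaks = c(0, 1, 10, 100, 1000)) {
    stopifnot(is(x, "CellCounts"), is(st, "AlignmentStats"))
    cells <- colnames(x)
    extra <- setdiff(cellIds(st), cells)
    missing <- setdiff(cells, cellIds(st))
    if (length(extra) || length(missing))
        stop(sprintf("cell sets differ; missing from stats: [%s]; extra in stats: [%s]",
                     paste(missing, collapse = ", "),
                     paste(extra, collapse = ", ")))
    s <- alignStats(st)[cells, , drop = FALSE]

    ratio <- function(num, den, what) {
        z <- den == 0
        if (any(z))
            warning(sprintf("%s: zero denominator for %d cell(s); imputed 0",
                            what, sum(z)))
        r <- ifelse(z, 0, num / ifelse(z, 1, den))
        as.numeric(r)
    }
    out <- data.frame(
        total_reads = as.numeric(s$total_reads),
        prop_mapped = ratio(s$mapped, s$total_reads, "prop_mapped"),
        prop_multimapped = ratio(s$multimapped, s$total_reads, "prop_multimapped"),
        prop_unmapped = ratio(s$unmapped, s$total_reads, "prop_unmapped"),
        prop_non_exonic = ratio(s$non_exonic, s$mapped, "prop_non_exonic"),
        prop_duplicated = ratio(s$duplicated, s$mapped, "prop_duplicated"),
        ercc_to_exonic = ratio(s$ercc_reads, s$exonic, "ercc_to_exonic"),
        row.names = cells)

    nm <- suppressWarnings(normalizeCounts(x))
    ercc <- rowData(x)$ercc
    ne <- assay(nm, "normalized")[!ercc, , drop = FALSE]
    raw <- assay(x, "counts")[!ercc, , drop = FALSE]

    out$n_detected_genes <- as.numeric(colSums(raw > 0))
    out$transcriptome_variance <-
        apply(log10(ne + 1e-6), 2, stats::var)

    detectedAny <- rowSums(ne > 0) > 0
    mv <- rowMeans(ne[detectedAny, , drop = FALSE])
    ctm <- suppressWarnings(
        as.numeric(stats::cor(ne[detectedAny, , drop = FALSE], mv,
                              method = "spearman")))
    bad <- is.na(ctm)
    if (any(bad))
        warning(sprintf("cell_to_mean_correlation undefined for %d cell(s); imputed 0",
                        sum(bad)))
    ctm[bad] <- 0
    out$cell_to_mean_correlation <- ctm

    hve <- tryCatch({
        dm <- computeDM(nm, window = window)
        mu <- rowMeans(ne)
        hi <- names(dm)[dm > 0 & mu[names(dm)] > stats::median(mu)]
        as.numeric(colSums(raw[hi, , drop = FALSE] > 0))
    }, error = function(e) {
        warning(sprintf("high-variance/high-expression set unavailable (%s); feature set to 0",
                        conditionMessage(e)))
        rep(0, length(cells))
    })
    out$n_high_var_high_expr <- hve

    cpm <- ne * 1e6
    edges <- c(binBreaks, Inf)
    for (b in seq_len(length(edges) - 1)) {
        out[[sprintf("n_genes_bin%d", b)]] <-
            as.numeric(colSums(cpm > edges[b] & cpm <= edges[b + 1]))
    }
    CellFeatures(as.matrix(out), kind = "technical", common = FALSE)
}

#' Assemble partial feature tables
#'
#' Column-binds feature tables over the same cells (names must be disjoint)
#' and flags the seven canonical cell-type-independent features
#' ([commonFeatureNames()]) where present.
#'
#' @param ... \linkS4class{CellFeatures} objects over identical cells.
#' @return A combined \linkS4class{CellFeatures}.
#' @export
assembleFeatures <- function(...) {
    parts <- list(...)
    stopifnot(length(parts) >= 1,
              all(vapply(parts, is, logical(1), "CellFeatures")))
    cells <- rownames(featureMatrix(parts[[1]]))
    for (p in parts[-1])
        if (!identical(rownames(featureMatrix(p)), cells))
            stop("feature tables cover different cells")
    nms <- unlist(lapply(parts, function(p) colnames(featureMatrix(p))))
    if (anyDuplicated(nms))
        stop(sprintf("duplicated feature name(s): %s",
                     paste(unique(nms[duplicated(nms)]), collapse = ", ")))
    vals <- do.call(cbind, lapply(parts, featureMatrix))
    kind <- unlist(lapply(parts, function(p) unname(featureKind(p))))
    CellFeatures(vals, kind = kind,
                 common = colnames(vals) %in% commonFeatureNames())
}

#' Extract the full feature table from counts, stats and gene sets
#'
#' Convenience wrapper: normalizes the counts, computes the biological
#' gene-set proportions and the technical features, and assembles them into
#' one table with the common-set flags.
#'
#' @inheritParams technicalFeatures
#' @param gs A \linkS4class{GeneSetList}.
#' @return A \linkS4class{CellFeatures}.
#' @export
extractFeatures <- function(x, st, gs, window = 50) {
    nm <- suppressWarnings(normalizeCounts(x))
    assembleFeatures(biologicalFeatures(nm, gs),
                     technicalFeatures(x, st, window = window))
}
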