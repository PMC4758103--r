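#' Paired t-tests on mean expression and noise per gene set
#'
#' For each gene set, member genes are paired across the two quality classes:
#' once on mean normalized expression (mean within LOW cells vs mean within
#' HIGH cells) and once on DM noise (distance-to-median computed within each
#' class separately). Each pairing is tested with a two-sided paired t-test;
#' p-values are adjusted across sets. The signed \code{-log10(p)} columns
#' (the t-statistic's sign times the negative log p) are the coordinates used
#' to display which functional categories are up- or downregulated / noisier
#' in low-quality cells.
#'
#' Genes without a defined DM in either class are excluded from the DM test.
#' A set whose paired differences are all exactly zero is reported with
#' \code{t = 0, p = 1}; a set with constant non-zero differences is
#' degenerate and reported as NA with a warning.
#'
#' @param nm A \linkS4class{NormalizedCounts} object.
#' @param labels A \linkS4class{QualityLabels} covering the cells of \code{nm}.
#' @param gs A \linkS4class{GeneSetList}.
#' @param adjust Multiple-testing adjustment across sets
#'   (\code{"BH"} default or \code{"bonferroni"}).
#' @param window DM rolling-median window (default 50).
#' @return data.frame with one row per set: genes used, t/p/adjusted p for the
#'   mean and DM tests, and the signed \code{-log10(p)} columns.
#' @export
goPairedTTest <- function(nm, labels, gs, adjust = c("BH", "bonferroni"),
                          window = 50) {
    stopifnot(is(nm, "NormalizedCounts"), is(labels, "QualityLabels"),
              is(gs, "GeneSetList"))
    adjust <- match.arg(adjust)
    q <- quality(labels)
    cells <- intersect(colnames(nm), cellIds(labels))
    low <- cells[q[cells] == "LOW"]
    high <- cells[q[cells] == "HIGH"]
    if (length(low) < 2 || length(high) < 2)
        stop("at least 2 cells per quality class are required")
    v <- assay(nm, "normalized")[!rowData(nm)$ercc, , drop = FALSE]
    meanLow <- rowMeans(v[, low, drop = FALSE])
    meanHigh <- rowMeans(v[, high, drop = FALSE])
    dmLow <- tryCatch(computeDM(nm, low, window), error = function(e) {
        warning(sprintf("DM unavailable for LOW cells: %s", conditionMessage(e)))
        setNames(numeric(0), character(0))
    })
    dmHigh <- tryCatch(computeDM(nm, high, window), error = function(e) {
        warning(sprintf("DM unavailable for HIGH cells: %s", conditionMessage(e)))
        setNames(numeric(0), character(0))
    })

    pairedT <- function(a, b, set, what) {
        d <- a - b
        if (length(d) < 2) return(c(NA_real_, NA_real_))
        if (stats::sd(d) == 0) {
            if (all(d == 0)) return(c(0, 1))
            warning(sprintf("set '%s': constant non-zero paired %s differences; test undefined",
                            set, what))
            return(c(NA_real_, NA_real_))
        }
        tt <- stats::t.test(a, b, paired = TRUE)
        c(unname(tt$statistic), tt$p.value)
    }

    sets <- geneSets(gs)
    res <- lapply(names(sets), function(nmset) {
        members <- intersect(sets[[nmset]], rownames(v))
        mt <- pairedT(meanLow[members], meanHigh[members], nmset, "mean")
        dgenes <- intersect(intersect(members, names(dmLow)), names(dmHigh))
        dt <- pairedT(dmLow[dgenes], dmHigh[dgenes], nmset, "DM")
        data.frame(set = nmset, n_genes_mean = length(members),
                   n_genes_dm = length(dgenes),
                   t_mean = mt[1], p_mean = mt[2],
                   t_dm = dt[1], p_dm = dt[2],
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj_mean <- stats::p.adjust(res$p_mean, method = adjust)
    res$p_adj_dm <- stats::p.adjust(res$p_dm, method = adjust)
    res$signed_log10_p_mean <- -log10(res$p_mean) * sign(res$t_mean)
    res$signed_log10_p_dm <- -log10(res$p_dm) * sign(res$t_dm)
    rownames(res) <- NULL
    res
}

#' Fisher's exact test for outlier enrichment
#'
#' Tests whether annotated cells are enriched among the cells flagged by the
#' unsupervised outlier detector, via the exact hypergeometric test on the
#' 2x2 outlier-by-annotation table. A degenerate table (all cells in one
#' category of either margin) returns p = 1 with a warning.
#'
#' @param outlier Logical per-cell outlier calls.
#' @param annotated Logical per-cell annotation (e.g. visibly damaged).
#' @param alternative \code{"greater"} (default: enrichment) or
#'   \code{"two.sided"}.
#' @return List with \code{p.value}, \code{odds.ratio} and the 2x2
#'   \code{table}.
#' @export
fisherEnrichment <- function(outlier, annotated,
                             alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    stopifnot(length(outlier) == length(annotated), length(outlier) >= 1)
    outlier <- as.logical(outlier)
    annotated <- as.logical(annotated)
    tab <- table(factor(outlier, c(TRUE, FALSE)),
                 factor(annotated, c(TRUE, FALSE)),
                 dnn = c("outlier", "annotated"))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        warning("degenerate 2x2 table (a margin is zero); p = 1")
        return(list(p.value = 1, odds.ratio = NA_real_, table = tab))
    }
    ft <- stats::fisher.test(tab, alternative = alternative)
    list(p.value = ft$p.value, odds.ratio = unname(ft$estimate), table = tab)
}

# vectorized confusion-table metrics; LOW is the positive class.
# MCC is defined 0 when any marginal is 0; other 0/0 ratios propagate NaN.
.confusionMetrics <- function(tp, tn, fp, fn, beta = 2) {
    b2 <- beta^2
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    acc <- (tn + tp) / (tn + tp + fn + fp)
    f <- (1 + b2) * tp / ((1 + b2) * tp + b2 * fn + fp)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- ifelse(den == 0, 0, (tp * tn - fp * fn) / ifelse(den == 0, 1, den))
    list(TP = tp, TN = tn, FP = fp, FN = fn, beta = beta,
         sensitivity = sens, specificity = spec, accuracy = acc,
         f_beta = f, mcc = mcc)
}

#' Classification accuracy metrics with LOW as the positive class
#'
#' Sensitivity (proportion of low-quality cells recovered), specificity
#' (proportion of high-quality cells kept), total accuracy, the F-beta score
#' \deqn{F_\beta = (1+\beta^2) TP / ((1+\beta^2) TP + \beta^2 FN + FP)}
#' and Matthews correlation coefficient. Because quality-control training
#' sets are typically imbalanced (about 80\% high / 20\% low quality), the
#' F-beta score with \code{beta = 2} is the default model-selection
#' criterion. MCC is defined as 0 when any marginal of the confusion table is
#' zero.
#'
#' @param predicted,truth \linkS4class{QualityLabels} objects (matched by
#'   cell id) or HIGH/LOW vectors of equal length.
#' @param beta Positive F-score weight (default 2).
#' @return Object of class \code{"metrics_report"}: a list with the confusion
#'   counts and the five metrics.
#' @export
#' @examples
#' classificationMetrics(c("LOW", "HIGH", "LOW"), c("LOW", "HIGH", "HIGH"))
classificationMetrics <- function(predicted, truth, beta = 2) {
    stopifnot(beta > 0)
    asq <- function(x) {
        if (is(x, "QualityLabels")) setNames(as.character(quality(x)), cellIds(x))
        else toupper(as.character(x))
    }
    p <- asq(predicted); t <- asq(truth)
    if (!is.null(names(p)) && !is.null(names(t)) &&
        nzchar(names(p)[1] %||% "")) {
        if (!setequal(names(p), names(t)))
            stop("predicted and truth cover different cells")
        t <- t[names(p)]
    } else if (length(p) != length(t)) {
        stop("predicted and truth have different lengths")
    }
    tp <- sum(p == "LOW" & t == "LOW")
    tn <- sum(p == "HIGH" & t == "HIGH")
    fp <- sum(p == "LOW" & t == "HIGH")
    fn <- sum(p == "HIGH" & t == "LOW")
    structure(.confusionMetrics(tp, tn, fp, fn, beta),
              class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
    cat(sprintf("Confusion (LOW = positive): TP=%d TN=%d FP=%d FN=%d\n",
                x$TP, x$TN, x$FP, x$FN))
    cat(sprintf("sensitivity=%.4f specificity=%.4f accuracy=%.4f F_%g=%.4f MCC=%.4f\n",
                x$sensitivity, x$specificity, x$accuracy, x$beta, x$f_beta,
                x$mcc))
    invisible(x)
}
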