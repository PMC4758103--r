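#' Center and scale a feature table
#'
#' Each feature is centered to mean 0 and scaled to unit variance.
#' Zero-variance features are left centered (scale fixed at 1) and flagged.
#' Stored parameters can be re-applied to new cells to reproduce the
#' training-time transform.
#'
#' @param ft A \linkS4class{CellFeatures} or numeric matrix (cells x
#'   features).
#' @param center,scale Optional stored parameters; computed when NULL.
#' @return List of class \code{"feature_scaling"}: \code{values} (scaled
#'   matrix), \code{center}, \code{scale}, \code{zeroVariance} (names of
#'   flagged features).
#' @export
scaleFeatures <- function(ft, center = NULL, scale = NULL) {
    v <- if (is(ft, "CellFeatures")) featureMatrix(ft) else as.matrix(ft)
    if (nrow(v) < 2 && is.null(center))
        stop("at least 2 cells are required to fit scaling parameters")
    if (is.null(center)) center <- colMeans(v)
    if (is.null(scale)) {
        scale <- apply(v, 2, stats::sd)
        scale[scale == 0] <- 1
    }
    zv <- colnames(v)[scale == 1 & apply(v, 2, function(x) all(x == x[1]))]
    out <- sweep(sweep(v, 2, center, "-"), 2, scale, "/")
    structure(list(values = out, center = center, scale = scale,
                   zeroVariance = zv),
              class = "feature_scaling")
}

#' Principal component analysis of the feature table
#'
#' Deterministic PCA of the scaled feature table. The sign of each component
#' is fixed by making its largest-magnitude loading positive, so repeated
#' runs (and implementations) agree.
#'
#' @param ft A \linkS4class{CellFeatures} or numeric matrix.
#' @param nComponents Number of components to keep (default: all).
#' @return List of class \code{"feature_pca"}: \code{scores} (cells x
#'   components), \code{loadings} (features x components),
#'   \code{explainedVariance}, and the stored \code{center}/\code{scale}.
#' @export
featurePCA <- function(ft, nComponents = NULL) {
    sc <- scaleFeatures(ft)
    v <- sc$values
    if (nrow(v) < 2) stop("at least 2 cells are required for PCA")
    maxComp <- min(nrow(v) - 1L, ncol(v))
    if (is.null(nComponents)) nComponents <- maxComp
    if (nComponents > maxComp)
        stop(sprintf("nComponents must be <= min(cells - 1, features) = %d",
                     maxComp))
    pr <- stats::prcomp(v, center = FALSE, scale. = FALSE)
    flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
    flip[flip == 0] <- 1
    rot <- sweep(pr$rotation, 2, flip, "*")
    scores <- sweep(pr$x, 2, flip, "*")
    k <- seq_len(nComponents)
    structure(list(scores = scores[, k, drop = FALSE],
                   loadings = rot[, k, drop = FALSE],
                   explainedVariance = pr$sdev[k]^2,
                   totalVariance = sum(pr$sdev^2),
                   center = sc$center, scale = sc$scale,
                   zeroVariance = sc$zeroVariance),
              class = "feature_pca")
}

#' Select cell-type-independent ("common") features by PCA loadings
#'
#' When cells from several cell types or protocols are pooled, the first two
#' principal components of the feature table separate the types; features
#' with extreme loadings on those components are cell-type specific. This
#' rule drops every feature whose PC1 or PC2 loading lies at or below the
#' \code{quantile} or at or above the \code{1 - quantile} empirical quantile
#' (type 7) of that component's loading values, then drops the explicitly
#' excluded features (those tied to the experimental setting, e.g. total
#' read count). Survivors are returned in the original feature order.
#'
#' @param pca A \code{"feature_pca"} object with at least 2 components.
#' @param quantile Trimming quantile in (0, 0.5); default 0.25 (quartiles).
#' @param exclude Feature names removed regardless of loadings.
#' @return Character vector of surviving feature names.
#' @export
selectCommonFeatures <- function(pca, quantile = 0.25,
                                 exclude = c("total_reads",
                                             "n_detected_genes")) {
    stopifnot(inherits(pca, "feature_pca"))
    if (quantile <= 0 || quantile >= 0.5)
        stop("'quantile' must be in (0, 0.5)")
    if (ncol(pca$loadings) < 2)
        stop("at least 2 principal components are required")
    feats <- rownames(pca$loadings)
    drop <- rep(FALSE, length(feats))
    for (comp in 1:2) {
        l <- pca$loadings[, comp]
        qs <- stats::quantile(l, c(quantile, 1 - quantile), type = 7,
                              names = FALSE)
        drop <- drop | l <= qs[1] | l >= qs[2]
    }
    survivors <- setdiff(feats[!drop], exclude)
    if (!length(survivors))
        stop("all features removed; use a smaller 'quantile'")
    survivors
}
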