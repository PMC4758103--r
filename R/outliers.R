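#' Unsupervised feature-based outlier detection
#'
#' Flags cells whose quality-feature profile lies outside the dense cluster
#' of typical cells: the feature table is scaled, projected onto its leading
#' principal components, a robust location and scatter are fitted with the
#' minimum covariance determinant (MCD), and cells whose squared robust
#' Mahalanobis distance exceeds the chi-squared quantile at \code{level}
#' (df = number of components) are flagged. Deterministic given the seed,
#' which is recorded in the report.
#'
#' @param ft A \linkS4class{CellFeatures} or numeric matrix (cells x
#'   features).
#' @param nComponents Number of principal components used (default 2).
#' @param level Chi-squared flagging level in (0.5, 1); default 0.975.
#' @param seed Integer seed controlling the MCD subset search.
#' @param features Optional feature-name subset (e.g.
#'   [commonFeatureNames()]) used instead of all features.
#' @return data.frame of class \code{"outlier_report"} with per-cell
#'   \code{robust_distance} and \code{is_outlier}; the squared-distance
#'   \code{threshold}, \code{nComponents}, \code{level} and \code{seed} are
#'   attached as attributes.
#' @export
detectOutliers <- function(ft, nComponents = 2, level = 0.975, seed = 1L,
                           features = NULL) {
    v <- if (is(ft, "CellFeatures")) featureMatrix(ft) else as.matrix(ft)
    if (!is.null(features)) {
        miss <- setdiff(features, colnames(v))
        if (length(miss))
            stop(sprintf("features not in table: %s",
                         paste(miss, collapse = ", ")))
        v <- v[, features, drop = FALSE]
    }
    if (level <= 0.5 || level >= 1) stop("'level' must be in (0.5, 1)")
    if (nrow(v) < 2 * (nComponents + 1))
        stop(sprintf("at least %d cells are required for %d component(s)",
                     2 * (nComponents + 1), nComponents))
    pca <- featurePCA(v, nComponents = nComponents)
    sc <- pca$scores
    rob <- withr::with_seed(as.integer(seed), tryCatch(
        MASS::cov.rob(sc, method = "mcd"),
        error = function(e) {
            warning(sprintf("MCD failed (%s); falling back to diagonal robust scatter",
                            conditionMessage(e)))
            list(center = apply(sc, 2, stats::median),
                 cov = diag(apply(sc, 2, stats::mad)^2,
                            ncol = ncol(sc)))
        }))
    covm <- rob$cov
    if (rcond(covm) < 1e-12) {
        warning("singular robust scatter; falling back to its diagonal")
        covm <- diag(diag(covm), ncol = ncol(covm))
    }
    d2 <- stats::mahalanobis(sc, rob$center, covm)
    thr <- stats::qchisq(level, df = ncol(sc))
    out <- data.frame(cell_id = rownames(v),
                      robust_distance = sqrt(d2),
                      is_outlier = d2 > thr,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "threshold") <- thr
    attr(out, "nComponents") <- ncol(sc)
    attr(out, "level") <- level
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("outlier_report", "data.frame")
    out
}
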