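#' Hyperparameter grid for the radial-kernel SVM
#'
#' Cartesian grid over the radial-kernel bandwidth \code{gamma}, the soft
#' margin \code{cost}, and the LOW-class weight multiplier (the HIGH class
#' has weight 1; upweighting LOW counters the typical 80/20 class
#' imbalance). The grid is ordered by (cost, gamma, weight) so that
#' score ties resolve toward the smoothest model.
#'
#' @param gamma,cost Positive numeric vectors of kernel/regularization
#'   values.
#' @param classWeightLow Positive LOW-class weight multipliers.
#' @return data.frame of class \code{"svm_grid"} with one row per
#'   combination.
#' @export
svmGrid <- function(gamma = 2^seq(-10, 2, by = 2),
                    cost = 2^seq(-4, 12, by = 2),
                    classWeightLow = c(1, 2, 4, 8)) {
    stopifnot(all(gamma > 0), all(cost > 0), all(classWeightLow > 0))
    g <- expand.grid(gamma = gamma, cost = cost,
                     classWeightLow = classWeightLow,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[order(g$cost, g$gamma, g$classWeightLow), , drop = FALSE]
    rownames(g) <- NULL
    class(g) <- c("svm_grid", "data.frame")
    g
}

#' A reduced grid for quick runs
#'
#' @return A small \code{"svm_grid"} (8 combinations) suitable for tests and
#'   examples.
#' @export
smallSvmGrid <- function() {
    svmGrid(gamma = 2^c(-6, -2), cost = 2^c(0, 4), classWeightLow = c(1, 4))
}

# stratified fold assignment; returns integer fold id per observation
.stratifiedFolds <- function(y, k, seed) {
    folds <- integer(length(y))
    withr::with_seed(as.integer(seed), {
        for (cl in levels(y)) {
            idx <- sample(which(y == cl))
            folds[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    folds
}

.fitSvm <- function(x, y, gamma, cost, classWeightLow) {
    e1071::svm(x = x, y = y, kernel = "radial", gamma = gamma, cost = cost,
               class.weights = c(HIGH = 1, LOW = classWeightLow),
               scale = FALSE)
}

.asQualityFactor <- function(labels, cells) {
    q <- quality(labels)
    miss <- setdiff(cells, names(q))
    if (length(miss))
        stop(sprintf("labels missing for cell(s): %s",
                     paste(utils::head(miss, 5), collapse = ", ")))
    factor(as.character(q[cells]), levels = .QUALITY_LEVELS)
}

.featureValues <- function(ft) {
    if (is(ft, "CellFeatures")) featureMatrix(ft) else as.matrix(ft)
}

# cross-validated mean F_beta for every grid point; scaling refit per fold
.gridScores <- function(x, y, grid, k, beta, seed) {
    folds <- .stratifiedFolds(y, k, seed)
    scores <- matrix(NA_real_, nrow(grid), k)
    for (f in seq_len(k)) {
        tr <- folds != f
        sc <- scaleFeatures(x[tr, , drop = FALSE])
        xtr <- sc$values
        xte <- scaleFeatures(x[!tr, , drop = FALSE], center = sc$center,
                             scale = sc$scale)$values
        for (g in seq_len(nrow(grid))) {
            fit <- .fitSvm(xtr, y[tr], grid$gamma[g], grid$cost[g],
                           grid$classWeightLow[g])
            pred <- stats::predict(fit, xte)
            m <- .confusionMetrics(sum(pred == "LOW" & y[!tr] == "LOW"),
                                   sum(pred == "HIGH" & y[!tr] == "HIGH"),
                                   sum(pred == "LOW" & y[!tr] == "HIGH"),
                                   sum(pred == "HIGH" & y[!tr] == "LOW"),
                                   beta)
            scores[g, f] <- if (is.nan(m$f_beta)) 0 else m$f_beta
        }
    }
    rowMeans(scores)
}

#' Select radial-SVM hyperparameters by cross-validated F-beta
#'
#' Stratified k-fold cross-validation over the grid; the combination with
#' the highest mean F-beta across folds wins, with ties broken toward
#' smaller cost, then smaller gamma, then smaller class weight.
#'
#' @param ft A \linkS4class{CellFeatures} or numeric matrix (cells x
#'   features).
#' @param labels A \linkS4class{QualityLabels} for those cells.
#' @param grid An [svmGrid()].
#' @param k Number of folds (default 10); both classes need at least k
#'   members.
#' @param beta F-beta weight for selection (default 2).
#' @param seed Integer seed for the fold shuffle.
#' @return List with the selected \code{gamma}, \code{cost},
#'   \code{classWeightLow} and its cross-validated \code{score}.
#' @export
tuneHyperparams <- function(ft, labels, grid = svmGrid(), k = 10, beta = 2,
                            seed = 1L) {
    x <- .featureValues(ft)
    y <- .asQualityFactor(labels, rownames(x))
    if (nlevels(droplevels(y)) < 2)
        stop("single class in labels; both HIGH and LOW are required")
    if (min(table(y)) < k)
        stop(sprintf("each class needs at least k = %d members", k))
    if (!nrow(grid)) stop("empty hyperparameter grid")
    scores <- .gridScores(x, y, grid, k, beta, seed)
    best <- which.max(scores)  # grid is tie-break ordered
    list(gamma = grid$gamma[best], cost = grid$cost[best],
         classWeightLow = grid$classWeightLow[best],
         score = scores[best])
}

#' Nested cross-validation of the SVM classifier
#'
#' The outer loop splits the cells into \code{kOuter} stratified folds and
#' holds each out in turn for accuracy measurement; the inner loop runs
#' [tuneHyperparams()] on the remaining folds. This separates hyperparameter
#' selection from accuracy estimation, avoiding selection-induced optimism.
#'
#' @inheritParams tuneHyperparams
#' @param kOuter,kInner Outer/inner fold counts (default 10 each).
#' @return List of class \code{"cv_report"}: \code{folds} (per-fold chosen
#'   hyperparameters and metrics) and \code{aggregate} (mean and sd of
#'   sensitivity, specificity and F-beta).
#' @export
nestedCV <- function(ft, labels, grid = svmGrid(), kOuter = 10, kInner = 10,
                     beta = 2, seed = 1L) {
    x <- .featureValues(ft)
    y <- .asQualityFactor(labels, rownames(x))
    if (min(table(y)) < kOuter)
        stop(sprintf("each class needs at least kOuter = %d members", kOuter))
    folds <- .stratifiedFolds(y, kOuter, seed)
    rows <- vector("list", kOuter)
    for (f in seq_len(kOuter)) {
        tr <- folds != f
        xtr <- x[tr, , drop = FALSE]
        ytr <- y[tr]
        innerLabels <- QualityLabels(rownames(xtr), as.character(ytr))
        hp <- tuneHyperparams(xtr, innerLabels, grid, k = kInner, beta = beta,
                              seed = seed + f)
        sc <- scaleFeatures(xtr)
        fit <- .fitSvm(sc$values, ytr, hp$gamma, hp$cost, hp$classWeightLow)
        xte <- scaleFeatures(x[!tr, , drop = FALSE], center = sc$center,
                             scale = sc$scale)$values
        pred <- stats::predict(fit, xte)
        m <- classificationMetrics(as.character(pred), as.character(y[!tr]),
                                   beta = beta)
        rows[[f]] <- data.frame(fold = f, gamma = hp$gamma, cost = hp$cost,
                                classWeightLow = hp$classWeightLow,
                                sensitivity = m$sensitivity,
                                specificity = m$specificity,
                                accuracy = m$accuracy, f_beta = m$f_beta,
                                mcc = m$mcc)
    }
    perFold <- do.call(rbind, rows)
    agg <- function(col) c(mean = mean(perFold[[col]], na.rm = TRUE),
                           sd = stats::sd(perFold[[col]], na.rm = TRUE))
    structure(list(folds = perFold,
                   aggregate = list(sensitivity = agg("sensitivity"),
                                    specificity = agg("specificity"),
                                    f_beta = agg("f_beta")),
                   beta = beta, kOuter = kOuter, kInner = kInner,
                   seed = as.integer(seed)),
              class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
    cat(sprintf("Nested %dx%d cross-validation (beta = %g, seed = %d)\n",
                x$kOuter, x$kInner, x$beta, x$seed))
    a <- x$aggregate
    cat(sprintf("  sensitivity %.3f +/- %.3f\n", a$sensitivity["mean"],
                a$sensitivity["sd"]))
    cat(sprintf("  specificity %.3f +/- %.3f\n", a$specificity["mean"],
                a$specificity["sd"]))
    cat(sprintf("  F_%g        %.3f +/- %.3f\n", x$beta, a$f_beta["mean"],
                a$f_beta["sd"]))
    invisible(x)
}

#' Train a majority-vote ensemble of radial-kernel SVMs
#'
#' Repeats the cross-validated hyperparameter selection \code{nMembers}
#' times with reshuffled folds (one derived seed per member), fits one SVM
#' on the full training table per selected combination, and stores the
#' scaling fitted on the training data. Repeated selection under different
#' shuffles lands on different hyperparameter combinations, which is what
#' gives the ensemble its diversity.
#'
#' @inheritParams tuneHyperparams
#' @param nMembers Ensemble size (default 50).
#' @param commonOnly If TRUE, restrict training to the features flagged as
#'   common in \code{ft}.
#' @return An \linkS4class{SVMEnsemble}.
#' @export
trainEnsemble <- function(ft, labels, grid = svmGrid(), nMembers = 50,
                          k = 10, beta = 2, seed = 1L, commonOnly = FALSE) {
    if (commonOnly) {
        stopifnot(is(ft, "CellFeatures"))
        ft <- ft[, which(isCommon(ft))]
    }
    x <- .featureValues(ft)
    y <- .asQualityFactor(labels, rownames(x))
    if (nlevels(droplevels(y)) < 2)
        stop("single class in labels; both HIGH and LOW are required")
    sc <- scaleFeatures(x)
    memberSeeds <- withr::with_seed(as.integer(seed),
                                    sample.int(.Machine$integer.max %/% 2,
                                               nMembers))
    members <- vector("list", nMembers)
    lab <- QualityLabels(rownames(x), as.character(y))
    for (i in seq_len(nMembers)) {
        hp <- tuneHyperparams(x, lab, grid, k = k, beta = beta,
                              seed = memberSeeds[i])
        fit <- .fitSvm(sc$values, y, hp$gamma, hp$cost, hp$classWeightLow)
        members[[i]] <- list(fit = fit, params = hp)
    }
    new("SVMEnsemble", members = members, featureNames = colnames(x),
        center = sc$center, scale = sc$scale, beta = beta,
        seed = as.integer(seed),
        labelCounts = setNames(as.integer(table(y)), levels(y)),
        version = "cellqc/ensemble/v1")
}

# majority vote over a members x cells character matrix of "HIGH"/"LOW";
# exact tie goes to LOW (discard questionable cells)
.majorityVote <- function(votes) {
    frac <- colMeans(votes == "LOW")
    list(label = ifelse(frac >= 0.5, "LOW", "HIGH"), lowFraction = frac)
}

#' Predict cell quality with an SVM ensemble
#'
#' Each member votes per cell after the stored training-time scaling is
#' applied; the majority determines the call and the LOW-vote fraction is
#' reported. An exact tie is called LOW. Extra features in \code{newdata}
#' are ignored with a warning; missing features are an error.
#'
#' @param object An \linkS4class{SVMEnsemble}.
#' @param newdata A \linkS4class{CellFeatures} or numeric matrix containing
#'   at least the model's features.
#' @param ... Ignored.
#' @return List with \code{labels} (\linkS4class{QualityLabels}) and
#'   \code{voteFraction} (named numeric LOW-vote fractions).
#' @export
setMethod("predict", "SVMEnsemble", function(object, newdata, ...) {
    x <- .featureValues(newdata)
    miss <- setdiff(object@featureNames, colnames(x))
    if (length(miss))
        stop(sprintf("missing feature(s): %s", paste(miss, collapse = ", ")))
    extra <- setdiff(colnames(x), object@featureNames)
    if (length(extra))
        warning(sprintf("ignoring %d extra feature(s): %s", length(extra),
                        paste(utils::head(extra, 5), collapse = ", ")))
    x <- x[, object@featureNames, drop = FALSE]
    xs <- scaleFeatures(x, center = object@center, scale = object@scale)$values
    votes <- t(vapply(object@members,
                      function(m) as.character(stats::predict(m$fit, xs)),
                      character(nrow(xs))))
    if (nrow(xs) == 1) votes <- matrix(votes, ncol = 1)
    colnames(votes) <- rownames(xs)
    mv <- .majorityVote(votes)
    list(labels = QualityLabels(rownames(xs), mv$label),
         voteFraction = mv$lowFraction)
})

#' Save / load an SVM ensemble
#'
#' The ensemble is stored as a single serialized archive with a schema
#' version tag; loading checks the tag and fails loudly on truncated or
#' foreign files.
#'
#' @param model An \linkS4class{SVMEnsemble}.
#' @param path File path for the model archive.
#' @return \code{saveEnsemble} invisibly returns \code{path};
#'   \code{loadEnsemble} returns the \linkS4class{SVMEnsemble}.
#' @export
saveEnsemble <- function(model, path) {
    stopifnot(is(model, "SVMEnsemble"))
    saveRDS(list(schema = model@version, model = model), path)
    invisible(path)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(path) {
    obj <- tryCatch(readRDS(path), error = function(e)
        stop(sprintf("corrupt or truncated model file '%s': %s", path,
                     conditionMessage(e))))
    if (!is.list(obj) || is.null(obj$schema))
        stop(sprintf("'%s' is not a cellqc model archive", path))
    if (!identical(obj$schema, "cellqc/ensemble/v1"))
        stop(sprintf("model schema mismatch: found '%s', expected 'cellqc/ensemble/v1'",
                     obj$schema))
    obj$model
}
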