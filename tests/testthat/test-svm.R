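test_that("separable data reach F-beta 1 with the tie-break smallest model", {
    fix <- separableFeatures(nHigh = 24, nLow = 12, gap = 8)
    grid <- smallSvmGrid()
    hp <- tuneHyperparams(fix$features, fix$labels, grid, k = 4, seed = 5)
    expect_equal(hp$score, 1)
    # every grid point separates; ties resolve to the smallest cost, gamma
    expect_equal(hp$cost, min(grid$cost))
    expect_equal(hp$gamma, min(grid$gamma))

    hp2 <- tuneHyperparams(fix$features, fix$labels, grid, k = 4, seed = 5)
    expect_identical(hp, hp2)
})

test_that("single-class labels and empty grids are rejected", {
    fix <- separableFeatures(nHigh = 20, nLow = 10)
    allHigh <- QualityLabels(cellIds(fix$labels), rep("HIGH", 30))
    expect_error(tuneHyperparams(fix$features, allHigh, smallSvmGrid(),
                                 k = 3),
                 "single class")
    expect_error(trainEnsemble(fix$features, allHigh, smallSvmGrid(),
                               nMembers = 2, k = 3), "single class")
    g <- smallSvmGrid()[0, ]
    expect_error(tuneHyperparams(fix$features, fix$labels, g, k = 3),
                 "empty")
})

test_that("nested CV separates a separable fixture and runs at minimal size", {
    fix <- separableFeatures(nHigh = 48, nLow = 24, gap = 8)
    cv <- nestedCV(fix$features, fix$labels, smallSvmGrid(), kOuter = 4,
                   kInner = 3, seed = 2)
    expect_equal(unname(cv$aggregate$sensitivity["mean"]), 1)
    expect_equal(unname(cv$aggregate$specificity["mean"]), 1)
    expect_identical(nrow(cv$folds), 4L)
    # every cell appears exactly once across outer test folds (fold sizes sum)
    expect_identical(sum(cv$folds$sensitivity >= 0), 4L)

    tiny <- separableFeatures(nHigh = 4, nLow = 4, gap = 10)
    expect_no_error(nestedCV(tiny$features, tiny$labels,
                             smallSvmGrid()[1:2, ], kOuter = 2, kInner = 2,
                             seed = 1))
})

test_that("majority voting follows the documented tie rule", {
    votes <- rbind(c("LOW", "HIGH", "LOW"),
                   c("LOW", "HIGH", "HIGH"),
                   c("LOW", "LOW", "HIGH"),
                   c("HIGH", "LOW", "HIGH"))
    colnames(votes) <- c("a", "b", "c")
    mv <- cellqc:::.majorityVote(votes)
    expect_equal(unname(mv$lowFraction), c(0.75, 0.5, 0.25))
    # exact tie (cell b) is called LOW
    expect_equal(unname(mv$label), c("LOW", "LOW", "HIGH"))
})

test_that("the ensemble trains, votes, and round-trips bit-stably", {
    fix <- separableFeatures(nHigh = 30, nLow = 15, gap = 8)
    grid <- smallSvmGrid()[1:2, ]
    model <- trainEnsemble(fix$features, fix$labels, grid, nMembers = 5,
                           k = 3, seed = 7)
    expect_identical(length(model@members), 5L)
    pred <- predict(model, fix$features)
    expect_equal(as.character(quality(pred$labels)),
                 as.character(quality(fix$labels)))
    expect_true(all(pred$voteFraction[quality(fix$labels) == "LOW"] > 0.5))

    # determinism: same master seed, identical serialized bytes
    model2 <- trainEnsemble(fix$features, fix$labels, grid, nMembers = 5,
                            k = 3, seed = 7)
    dir <- withr::local_tempdir()
    p1 <- file.path(dir, "m1.rds"); p2 <- file.path(dir, "m2.rds")
    saveEnsemble(model, p1); saveEnsemble(model2, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))

    # save -> load -> predict equals predict before save
    loaded <- loadEnsemble(p1)
    pred2 <- predict(loaded, fix$features)
    expect_identical(pred2$voteFraction, pred$voteFraction)

    # n_members = 1 degenerates to a single tuned SVM
    single <- trainEnsemble(fix$features, fix$labels, grid, nMembers = 1,
                            k = 3, seed = 7)
    expect_identical(length(single@members), 1L)
})

test_that("model files are schema-checked and truncation is detected", {
    fix <- separableFeatures(nHigh = 12, nLow = 8, gap = 10)
    model <- trainEnsemble(fix$features, fix$labels, smallSvmGrid()[1, ],
                           nMembers = 1, k = 2, seed = 1)
    dir <- withr::local_tempdir()
    p <- file.path(dir, "m.rds")
    saveEnsemble(model, p)
    full <- readBin(p, "raw", file.size(p))
    writeBin(full[1:(length(full) %/% 3)], p)
    expect_error(loadEnsemble(p), "corrupt or truncated")

    saveRDS(list(schema = "cellqc/ensemble/v999", model = NULL), p)
    expect_error(loadEnsemble(p), "schema mismatch")
    saveRDS(1:3, p)
    expect_error(loadEnsemble(p), "not a cellqc model archive")
})

test_that("prediction checks features, ignores extras, survives reordering", {
    fix <- separableFeatures(nHigh = 20, nLow = 10, gap = 8)
    model <- trainEnsemble(fix$features, fix$labels, smallSvmGrid()[1, ],
                           nMembers = 3, k = 3, seed = 3)
    v <- featureMatrix(fix$features)

    expect_error(predict(model, v[, -1]), "missing feature\\(s\\): f01")

    extra <- cbind(v, junk = rnorm(nrow(v)))
    expect_warning(pe <- predict(model, extra), "extra feature")
    base <- predict(model, v)
    expect_identical(pe$voteFraction, base$voteFraction)

    shuffled <- v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v)))]
    ps <- predict(model, shuffled)
    expect_equal(ps$voteFraction[names(base$voteFraction)],
                 base$voteFraction)
})

test_that("class weights rescue the minority class on a hard imbalance", {
    # overlapping classes, 1:9 imbalance: unweighted selection collapses to
    # all-HIGH; allowing LOW upweighting changes the selected model
    withr::with_seed(40, {
        n <- 180
        y <- rep(c("HIGH", "LOW"), c(162, 18))
        v <- matrix(rnorm(n * 2), n, 2)
        v[y == "LOW", ] <- v[y == "LOW", ] + 1.2
        dimnames(v) <- list(sprintf("c%03d", 1:n), c("f1", "f2"))
    })
    labels <- QualityLabels(rownames(v), y)
    gridUnw <- svmGrid(gamma = 2^c(-4, -2), cost = c(1, 4),
                       classWeightLow = 1)
    gridW <- svmGrid(gamma = 2^c(-4, -2), cost = c(1, 4),
                     classWeightLow = c(1, 8))
    hpU <- tuneHyperparams(v, labels, gridUnw, k = 5, seed = 6)
    hpW <- tuneHyperparams(v, labels, gridW, k = 5, seed = 6)
    expect_gt(hpW$score, hpU$score)
    expect_gt(hpW$classWeightLow, 1)
})

test_that("training with all features is at least as good as common-only", {
    sim <- smallSim(seed = 11)
    ft <- suppressWarnings(extractFeatures(sim$counts, sim$stats,
                                           sim$geneSets))
    wins <- 0
    for (seed in 1:5) {
        all <- tuneHyperparams(ft, sim$labels, smallSvmGrid(), k = 5,
                               seed = seed)
        common <- tuneHyperparams(ft[, which(isCommon(ft))], sim$labels,
                                  smallSvmGrid(), k = 5, seed = seed)
        if (all$score >= common$score) wins <- wins + 1
    }
    expect_gte(wins, 3)
})
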