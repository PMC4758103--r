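test_that("DM is zero under constant CV^2 and 1.0 for a 10x inflated pair", {
    nm <- constantCV2Normalized(nPairs = 10, nCells = 8)
    dm <- computeDM(nm, window = 5)
    expect_equal(unname(dm), rep(0, 20), tolerance = 1e-12)

    amp <- rep(1, 10); amp[4] <- sqrt(10)  # CV^2 inflated exactly 10x
    nm2 <- constantCV2Normalized(nPairs = 10, nCells = 8, amp = amp)
    dm2 <- computeDM(nm2, window = 5)
    expect_equal(unname(dm2[c("G007", "G008")]), c(1, 1), tolerance = 1e-9)
    expect_equal(unname(dm2[setdiff(names(dm2), c("G007", "G008"))]),
                 rep(0, 18), tolerance = 1e-9)
})

test_that("DM excludes unexpressed genes and validates its window", {
    nm <- constantCV2Normalized(nPairs = 10, nCells = 8)
    expect_error(computeDM(nm, window = 2), "at least 3")
    expect_error(computeDM(nm, window = 50), "window")
    # a zero row never appears in the output
    v <- assay(nm, "normalized")
    v2 <- rbind(v, dead = 0)
    cc <- countsFromProportions(sweep(v2, 2, colSums(v2), "/"))
    dm <- computeDM(normalizeCounts(cc), window = 5)
    expect_false("dead" %in% names(dm))
})

test_that("paired gene-set t-test matches the closed-form Student t", {
    # paired differences (1,2,3): t = 2/(1/sqrt(3)), two-sided p at df = 2
    v <- matrix(0, 3, 4)
    rownames(v) <- c("g1", "g2", "g3")
    colnames(v) <- c("l1", "l2", "h1", "h2")
    base <- c(0.2, 0.3, 0.5)
    shift <- c(1, 2, 3) / 60
    v[, c("h1", "h2")] <- base
    v[, c("l1", "l2")] <- base + shift
    v <- sweep(v, 2, colSums(v), "/")
    # re-derive the realized paired differences after renormalization
    dExp <- rowMeans(v[, 1:2]) - rowMeans(v[, 3:4])
    tExp <- mean(dExp) / (sd(dExp) / sqrt(3))
    pExp <- 2 * pt(-abs(tExp), df = 2)

    nm <- normalizeCounts(countsFromProportions(v))
    labels <- QualityLabels(colnames(v), c("LOW", "LOW", "HIGH", "HIGH"))
    res <- suppressWarnings(
        goPairedTTest(nm, labels, GeneSetList(list(s = rownames(v))),
                      window = 50))
    expect_equal(res$t_mean, tExp, tolerance = 1e-12)
    expect_equal(res$p_mean, pExp, tolerance = 1e-12)
    expect_equal(res$signed_log10_p_mean, -log10(pExp) * sign(tExp))

    # the textbook case: unnormalized differences (1,2,3); for df = 2 the
    # two-sided p has the closed form 1 - t/sqrt(t^2 + 2)
    tRef <- 2 / (1 / sqrt(3))
    expect_equal(tRef, 3.4641016, tolerance = 1e-6)
    expect_equal(2 * pt(-tRef, 2), 1 - tRef / sqrt(tRef^2 + 2),
                 tolerance = 1e-12)
    expect_equal(2 * pt(-tRef, 2), 0.0741799, tolerance = 1e-6)
})

test_that("identical classes give t = 0, p = 1; label swap negates t", {
    sim <- smallSim(seed = 6)
    nm <- suppressWarnings(normalizeCounts(sim$counts))
    cells <- colnames(nm)
    # identical per-gene means: same cells in both classes via duplication
    v <- assay(nm, "normalized")[!erccMask(nm), 1:6]
    v <- sweep(v, 2, colSums(v), "/")
    dup <- cbind(v, v)
    colnames(dup) <- sprintf("c%02d", 1:12)
    # identical library size for paired columns keeps the duplicated cells
    # bit-identical through normalization
    nmd <- normalizeCounts(countsFromProportions(dup, lib = rep(1000, 12)))
    lab <- QualityLabels(colnames(dup), rep(c("LOW", "HIGH"), each = 6))
    gs <- sim$geneSets
    res <- suppressWarnings(goPairedTTest(nmd, lab, gs))
    expect_true(all(res$t_mean == 0))
    expect_true(all(res$p_mean == 1))
    expect_true(all(res$p_dm == 1, na.rm = TRUE))

    # antisymmetry on a real contrast
    labels <- sim$labels
    flipped <- QualityLabels(cellIds(labels),
                             ifelse(quality(labels) == "LOW", "HIGH", "LOW"))
    r1 <- suppressWarnings(goPairedTTest(nm, labels, gs))
    r2 <- suppressWarnings(goPairedTTest(nm, flipped, gs))
    expect_equal(r1$t_mean, -r2$t_mean, tolerance = 1e-9)
    expect_equal(r1$p_mean, r2$p_mean, tolerance = 1e-12)
    expect_equal(r1$t_dm, -r2$t_dm, tolerance = 1e-9)
})

test_that("fisher enrichment matches exact hypergeometric enumeration", {
    # both annotated cells are outliers in a 2+2 population
    r <- fisherEnrichment(c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(r$p.value, 1 / 6, tolerance = 1e-12)

    # independent 2x2 table of ones: tail from the observed count
    r2 <- fisherEnrichment(c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(r2$p.value, enumFisherP(matrix(1, 2, 2), "greater"))
    expect_equal(r2$p.value, 5 / 6, tolerance = 1e-12)

    expect_warning(r3 <- fisherEnrichment(logical(4), c(TRUE, TRUE, FALSE,
                                                        FALSE)),
                   "degenerate")
    expect_equal(r3$p.value, 1)

    withr::with_seed(8, for (i in 1:25) {
        o <- sample(c(TRUE, FALSE), 14, replace = TRUE)
        a <- sample(c(TRUE, FALSE), 14, replace = TRUE)
        if (length(unique(o)) < 2 || length(unique(a)) < 2) next
        for (alt in c("greater", "two.sided")) {
            r <- fisherEnrichment(o, a, alternative = alt)
            expect_equal(r$p.value, enumFisherP(r$table, alt),
                         tolerance = 1e-12)
        }
    })
})

test_that("classification metrics follow their defining formulas", {
    m <- classificationMetrics(rep(c("LOW", "HIGH"), c(5, 15)),
                               rep("LOW", 20))
    expect_equal(m$sensitivity, 0.25)

    # TP=10, FN=10, FP=10, beta=2 -> 50/100
    pred <- rep(c("LOW", "HIGH", "LOW"), each = 10)
    truth <- rep(c("LOW", "LOW", "HIGH"), each = 10)
    m2 <- classificationMetrics(pred, truth, beta = 2)
    expect_equal(m2$f_beta, 0.5)

    perfect <- classificationMetrics(c("LOW", "LOW", "HIGH"),
                                     c("LOW", "LOW", "HIGH"))
    expect_equal(perfect$sensitivity, 1)
    expect_equal(perfect$specificity, 1)
    expect_equal(perfect$accuracy, 1)
    expect_equal(perfect$f_beta, 1)
    expect_equal(perfect$mcc, 1)

    # cell-id matching, not positional
    p <- QualityLabels(c("a", "b"), c("LOW", "HIGH"))
    t2 <- QualityLabels(c("b", "a"), c("HIGH", "LOW"))
    expect_equal(classificationMetrics(p, t2)$accuracy, 1)
    t3 <- QualityLabels(c("a", "c"), c("LOW", "HIGH"))
    expect_error(classificationMetrics(p, t3), "different cells")
})

test_that("F-beta is monotone in TP and antitone in FP and FN", {
    grid <- expand.grid(tp = 0:6, tn = 3, fp = 0:6, fn = 0:6)
    for (beta in c(0.5, 1, 2)) {
        f <- function(tp, fp, fn)
            cellqc:::.confusionMetrics(tp, 3, fp, fn, beta)$f_beta
        base <- f(grid$tp, grid$fp, grid$fn)
        up <- f(grid$tp + 1, grid$fp, grid$fn)
        expect_true(all(up >= base, na.rm = TRUE))
        moreFp <- f(grid$tp, grid$fp + 1, grid$fn)
        expect_true(all(moreFp <= base, na.rm = TRUE))
        moreFn <- f(grid$tp, grid$fp, grid$fn + 1)
        expect_true(all(moreFn <= base, na.rm = TRUE))
    }
})

test_that("MCC degenerate marginals are reported as 0", {
    m <- classificationMetrics(rep("LOW", 4), rep(c("LOW", "HIGH"), 2))
    expect_equal(m$mcc, 0)  # no HIGH predictions: a zero marginal
})
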