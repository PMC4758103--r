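test_that("normalization divides by the non-ERCC total and flags empty cells", {
    m <- matrix(c(2, 3, 5, 10), 4, 1,
                dimnames = list(c("G1", "G2", "G3", "ERCC-1"), "c1"))
    nm <- normalizeCounts(CellCounts(m))
    expect_equal(assay(nm, "normalized")[, 1],
                 c(G1 = 0.2, G2 = 0.3, G3 = 0.5, `ERCC-1` = 1.0))

    # scale invariance: multiplying one cell's counts leaves proportions fixed
    m2 <- cbind(c1 = c(2, 3, 5, 10), c2 = 7 * c(2, 3, 5, 10))
    rownames(m2) <- rownames(m)
    nm2 <- normalizeCounts(CellCounts(m2))
    expect_equal(assay(nm2, "normalized")[, "c1"],
                 assay(nm2, "normalized")[, "c2"])

    m3 <- cbind(m, empty = c(0, 0, 0, 4))
    expect_warning(nm3 <- normalizeCounts(CellCounts(m3)), "zero non-ERCC")
    expect_true(all(assay(nm3, "normalized")[, "empty"] == 0))
    expect_identical(unname(colData(nm3)$zero_total), c(FALSE, TRUE))
})

test_that("biological features sum member proportions and partition to 1", {
    v <- matrix(c(0.2, 0.3, 0.5,
                  0.25, 0.35, 0.4), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
    nm <- normalizeCounts(countsFromProportions(v))
    gs <- GeneSetList(list(pair = c("g1", "g2"), all = c("g1", "g2", "g3"),
                           third = "g3"))
    ft <- biologicalFeatures(nm, gs)
    fm <- featureMatrix(ft)
    expect_equal(fm[, "pair"], c(c1 = 0.5, c2 = 0.6))
    expect_equal(fm[, "all"], c(c1 = 1, c2 = 1))
    # a partition of all non-ERCC genes sums to 1 per cell
    expect_equal(unname(fm[, "pair"] + fm[, "third"]), c(1, 1))

    expect_warning(ft2 <- biologicalFeatures(nm, GeneSetList(list(none = "gX"))),
                   "no genes")
    expect_true(all(featureMatrix(ft2) == 0))
    expect_error(biologicalFeatures(nm, GeneSetList(list())), "empty")
})

test_that("technical ratio features match the read-accounting arithmetic", {
    m <- matrix(c(10, 20, 40, 7), 4, 1,
                dimnames = list(c("G1", "G2", "G3", "ERCC-1"), "c1"))
    cc <- CellCounts(m)
    st <- AlignmentStats(statsTable("c1"))
    ft <- suppressWarnings(technicalFeatures(cc, st))
    fm <- featureMatrix(ft)[1, ]
    expect_equal(fm[["prop_mapped"]], 0.9)
    expect_equal(fm[["prop_multimapped"]], 0.05)
    expect_equal(fm[["prop_unmapped"]], 0.1)
    expect_equal(fm[["prop_non_exonic"]], 20 / 90)
    expect_equal(fm[["prop_duplicated"]], 30 / 90)
    expect_equal(fm[["ercc_to_exonic"]], 0.1)
    expect_equal(fm[["total_reads"]], 100)
    expect_equal(fm[["n_detected_genes"]], 3)
})

test_that("bin counts follow CPM decades and sum to detected genes", {
    # single expressed gene: CPM = 1e6 -> top bin
    m <- matrix(c(5, 0, 0), 3, 1,
                dimnames = list(c("G1", "G2", "G3"), "c1"))
    st <- AlignmentStats(statsTable("c1", ercc_reads = 0))
    ft <- suppressWarnings(technicalFeatures(CellCounts(m), st))
    fm <- featureMatrix(ft)[1, ]
    expect_equal(fm[["n_detected_genes"]], 1)
    expect_equal(fm[["n_genes_bin5"]], 1)
    expect_equal(sum(fm[sprintf("n_genes_bin%d", 1:4)]), 0)

    sim <- smallSim(seed = 5)
    ftbl <- suppressWarnings(
        technicalFeatures(sim$counts, sim$stats))
    fm2 <- featureMatrix(ftbl)
    bins <- fm2[, sprintf("n_genes_bin%d", 1:5)]
    expect_equal(unname(rowSums(bins)), unname(fm2[, "n_detected_genes"]))
})

test_that("cell-to-mean correlation is 1 for identical cells", {
    m <- matrix(rep(c(3, 7, 11, 2), 2), 4, 2,
                dimnames = list(sprintf("G%d", 1:4), c("c1", "c2")))
    st <- AlignmentStats(statsTable(c("c1", "c2"), ercc_reads = 0))
    ft <- suppressWarnings(technicalFeatures(CellCounts(m), st))
    expect_equal(unname(featureMatrix(ft)[, "cell_to_mean_correlation"]),
                 c(1, 1))
})

test_that("proportion features are invariant to per-cell scaling", {
    sim <- smallSim(seed = 2)
    ft1 <- suppressWarnings(extractFeatures(sim$counts, sim$stats,
                                            sim$geneSets))
    k <- 3  # scale every cell's counts and read accounting by k
    m <- assay(sim$counts, "counts") * k
    cc2 <- CellCounts(m, erccPrefix = "ERCC-")
    s <- alignStats(sim$stats) * k
    st2 <- AlignmentStats(cbind(cell_id = cellIds(sim$stats), s))
    ft2 <- suppressWarnings(extractFeatures(cc2, st2, sim$geneSets))
    props <- c("go_cytoplasm", "mtDNA_encoded", "mito_localized",
               "prop_mapped", "prop_multimapped", "prop_unmapped",
               "prop_non_exonic", "prop_duplicated", "ercc_to_exonic",
               "transcriptome_variance", "cell_to_mean_correlation")
    expect_equal(featureMatrix(ft1)[, props], featureMatrix(ft2)[, props],
                 tolerance = 1e-12)
})

test_that("feature assembly concatenates, flags the common seven and rejects collisions", {
    sim <- smallSim(seed = 3)
    nm <- suppressWarnings(normalizeCounts(sim$counts))
    bio <- biologicalFeatures(nm, sim$geneSets)
    tech <- suppressWarnings(technicalFeatures(sim$counts, sim$stats))
    ft <- assembleFeatures(bio, tech)
    expect_identical(ncol(featureMatrix(ft)), 26L)
    expect_setequal(names(which(isCommon(ft))), commonFeatureNames())
    expect_error(assembleFeatures(bio, bio), "duplicated feature")
    expect_error(assembleFeatures(bio, tech[1:3, ]), "different cells")
})

test_that("cell-set mismatches between matrix and stats are reported", {
    m <- tinyCountMatrix()
    st <- AlignmentStats(statsTable(c("cellA", "cellX")))
    expect_error(suppressWarnings(technicalFeatures(CellCounts(m), st)),
                 "cellB.*cellX|cellX.*cellB")
})

test_that("feature extraction is deterministic", {
    sim <- smallSim(seed = 4)
    f1 <- suppressWarnings(extractFeatures(sim$counts, sim$stats,
                                           sim$geneSets))
    f2 <- suppressWarnings(extractFeatures(sim$counts, sim$stats,
                                           sim$geneSets))
    expect_identical(featureMatrix(f1), featureMatrix(f2))
})
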