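#' Parameters for the synthetic single-cell QC dataset
#'
#' Defines the generative conditions the package's tests run under: an
#' imbalanced population (by default 160 high-quality cells and 40
#' low-quality cells — 24 broken, 8 empty wells, 8 multiples — the 80/20
#' class mix typical of annotated training sets), a log-normal gene
#' expression program sampled by negative-binomial counts, a fixed absolute
#' amount of ERCC spike-in per well, and the damage mechanisms the features
#' are built to detect:
#' \itemize{
#'   \item broken cells lose cytoplasmic transcripts (retention
#'     \code{brokenRetention}) while mitochondrially encoded RNA is
#'     physically protected (and further enriched by \code{mtdnaAmp}), their
#'     mapping rate drops and their non-exonic read fraction rises;
#'   \item empty wells contain almost no endogenous RNA, so the fixed
#'     spike-in dominates (\code{emptyErccDominance} of expected reads);
#'   \item multiples pool two cells: inflated library and a union of two
#'     gene-on masks (more detected genes);
#'   \item deceptive cells carry the broken expression profile but are
#'     labeled HIGH with subtype \code{deceptive}, emulating cells that look
#'     intact under the microscope.
#' }
#'
#' @param nHigh,nBroken,nEmpty,nMultiple,nDeceptive Cell counts per class.
#' @param nGenes,nErcc Number of endogenous genes and ERCC spike-in rows.
#' @param libMean,libSdLog Log-normal library-size model (expected
#'   endogenous reads per high-quality cell).
#' @param dispersion Negative-binomial size parameter for endogenous genes.
#' @param erccFrac Expected ERCC share of reads in a high-quality cell.
#' @param geneOnFrac Fraction of genes active in any one cell.
#' @param cellNoiseSdLog Per-cell log-normal jitter of the gene program.
#' @param brokenRetention Cytoplasmic retention fraction in broken cells
#'   (in (0,1)).
#' @param mtdnaAmp Relative mtDNA enrichment factor in broken cells (> 1).
#' @param brokenMappedDecrement,brokenNonExonicIncrement,
#'   brokenMultimapIncrement Shifts of the alignment rates in broken (and
#'   deceptive) cells.
#' @param emptyErccDominance Expected ERCC share of reads in empty wells.
#' @param multipleLibFactor Library-size multiplier for multiples.
#' @param mapRate,nonExonicFrac,multimapRate,dupRate Baseline alignment
#'   rates of high-quality cells.
#' @param rateConcentration Beta concentration of the per-cell rate jitter.
#' @param seed Integer seed; all randomness derives from it.
#' @return Validated list of class \code{"sim_params"}.
#' @export
simParams <- function(nHigh = 160, nBroken = 24, nEmpty = 8, nMultiple = 8,
                      nDeceptive = 0, nGenes = 2000, nErcc = 50,
                      libMean = 50000, libSdLog = 0.3, dispersion = 2,
                      erccFrac = 0.05, geneOnFrac = 0.7,
                      cellNoiseSdLog = 0.2,
                      brokenRetention = 0.15, mtdnaAmp = 2,
                      brokenMappedDecrement = 0.2,
                      brokenNonExonicIncrement = 0.15,
                      brokenMultimapIncrement = 0.05,
                      emptyErccDominance = 0.9, multipleLibFactor = 2,
                      mapRate = 0.8, nonExonicFrac = 0.15,
                      multimapRate = 0.05, dupRate = 0.3,
                      rateConcentration = 200, seed = 1L) {
    p <- as.list(environment())
    with(p, {
        stopifnot(nHigh >= 0, nBroken >= 0, nEmpty >= 0, nMultiple >= 0,
                  nDeceptive >= 0, nGenes > 400, nErcc >= 2,
                  libMean > 0, dispersion > 0,
                  erccFrac > 0, erccFrac < 1,
                  geneOnFrac > 0, geneOnFrac <= 1,
                  brokenRetention > 0, brokenRetention < 1, mtdnaAmp >= 1,
                  brokenMappedDecrement >= 0, brokenMappedDecrement < mapRate,
                  emptyErccDominance > 0, emptyErccDominance < 1,
                  multipleLibFactor >= 1,
                  mapRate > 0, mapRate < 1, nonExonicFrac > 0,
                  nonExonicFrac + brokenNonExonicIncrement < 1,
                  multimapRate > 0, multimapRate + brokenMultimapIncrement < 1,
                  dupRate > 0, dupRate < 1)
    })
    structure(p, class = "sim_params")
}

.rbetaMean <- function(n, mean, conc) stats::rbeta(n, mean * conc,
                                                   (1 - mean) * conc)

#' Simulate a synthetic QC dataset
#'
#' Generates a count matrix, matching alignment statistics (satisfying the
#' read-accounting invariants by construction), the gene-set collection the
#' biological features are scored against, and the ground-truth quality
#' labels. Identical parameters and seed give identical output.
#'
#' @param p A [simParams()] object.
#' @return List with elements \code{counts} (\linkS4class{CellCounts}),
#'   \code{stats} (\linkS4class{AlignmentStats}), \code{geneSets}
#'   (\linkS4class{GeneSetList}), \code{labels}
#'   (\linkS4class{QualityLabels}) and \code{params}.
#' @export
#' @examples
#' sim <- simulateDataset(simParams(nHigh = 20, nBroken = 4, nEmpty = 2,
#'                                  nMultiple = 2, nGenes = 500, seed = 7))
#' table(quality(sim$labels))
simulateDataset <- function(p = simParams()) {
    stopifnot(inherits(p, "sim_params"))
    withr::with_seed(as.integer(p$seed), .simulate(p))
}

.simulate <- function(p) {
    geneIds <- sprintf("G%05d", seq_len(p$nGenes))
    erccIds <- sprintf("ERCC-%05d", seq_len(p$nErcc))

    # dataset-level expression program and gene-set memberships
    prog <- exp(stats::rnorm(p$nGenes, 0, 1.5))
    prog <- prog / sum(prog)
    mtdna <- sort(sample.int(p$nGenes, 37))
    rest <- setdiff(seq_len(p$nGenes), mtdna)
    pick <- function(pool, n) sort(sample(pool, n))
    sets <- list(
        go_cytoplasm = geneIds[pick(rest, round(0.4 * p$nGenes))],
        go_membrane = geneIds[pick(seq_len(p$nGenes), round(0.15 * p$nGenes))],
        go_mitochondrion = geneIds[sort(c(mtdna, pick(rest, 80)))],
        go_metabolism = geneIds[pick(seq_len(p$nGenes), round(0.2 * p$nGenes))],
        go_extracellular_region = geneIds[pick(rest, round(0.05 * p$nGenes))],
        go_ribosome = geneIds[pick(seq_len(p$nGenes), 50)],
        go_programmed_cell_death = geneIds[pick(seq_len(p$nGenes), 60)],
        housekeeping = geneIds[pick(seq_len(p$nGenes), 80)],
        mtDNA_encoded = geneIds[mtdna],
        mito_localized = geneIds[sort(c(mtdna, pick(rest, 263)))])

    # fixed absolute spike-in amount per well
    erccProg <- exp(stats::rnorm(p$nErcc, 0, 1))
    erccProg <- erccProg / sum(erccProg)
    erccTotal <- p$erccFrac / (1 - p$erccFrac) * p$libMean
    erccMu <- erccProg * erccTotal

    classes <- c(rep("high", p$nHigh), rep("broken", p$nBroken),
                 rep("empty", p$nEmpty), rep("multiple", p$nMultiple),
                 rep("deceptive", p$nDeceptive))
    nCells <- length(classes)
    cellIds <- sprintf("cell_%04d", seq_len(nCells))

    counts <- matrix(0, p$nGenes + p$nErcc, nCells,
                     dimnames = list(c(geneIds, erccIds), cellIds))
    brokenLike <- classes %in% c("broken", "deceptive")

    for (i in seq_len(nCells)) {
        lib <- stats::rlnorm(1, log(p$libMean), p$libSdLog)
        mask <- stats::rbinom(p$nGenes, 1, p$geneOnFrac)
        if (classes[i] == "multiple") {
            mask <- pmax(mask, stats::rbinom(p$nGenes, 1, p$geneOnFrac))
            lib <- lib * p$multipleLibFactor
        }
        w <- prog * mask * exp(stats::rnorm(p$nGenes, 0, p$cellNoiseSdLog))
        e <- lib * w / sum(w)
        if (brokenLike[i]) {
            e[-mtdna] <- e[-mtdna] * p$brokenRetention
            e[mtdna] <- e[mtdna] * p$mtdnaAmp
        } else if (classes[i] == "empty") {
            e <- e * (erccTotal * (1 - p$emptyErccDominance) /
                      (p$emptyErccDominance * sum(e)))
        }
        counts[seq_len(p$nGenes), i] <-
            stats::rnbinom(p$nGenes, mu = e, size = p$dispersion)
        counts[p$nGenes + seq_len(p$nErcc), i] <-
            stats::rnbinom(p$nErcc, mu = erccMu, size = 10)
    }

    # alignment accounting consistent with the matrix
    sEnd <- colSums(counts[seq_len(p$nGenes), , drop = FALSE])
    sErcc <- colSums(counts[p$nGenes + seq_len(p$nErcc), , drop = FALSE])
    exonic <- sEnd + sErcc
    neMean <- ifelse(brokenLike, p$nonExonicFrac + p$brokenNonExonicIncrement,
                     p$nonExonicFrac)
    mapMean <- ifelse(brokenLike, p$mapRate - p$brokenMappedDecrement,
                      p$mapRate)
    mmMean <- ifelse(brokenLike, p$multimapRate + p$brokenMultimapIncrement,
                     p$multimapRate)
    ne <- .rbetaMean(nCells, neMean, p$rateConcentration)
    mr <- .rbetaMean(nCells, mapMean, p$rateConcentration)
    mm <- .rbetaMean(nCells, mmMean, p$rateConcentration)
    dup <- .rbetaMean(nCells, p$dupRate, p$rateConcentration)
    nonExonic <- round(exonic * ne / (1 - ne))
    mapped <- exonic + nonExonic
    total <- pmax(mapped, round(mapped / mr))
    stats <- data.frame(
        cell_id = cellIds,
        total_reads = total,
        mapped = mapped,
        multimapped = stats::rbinom(nCells, total, mm),
        unmapped = total - mapped,
        exonic = exonic,
        non_exonic = nonExonic,
        duplicated = stats::rbinom(nCells, mapped, dup),
        ercc_reads = sErcc,
        stringsAsFactors = FALSE)

    labels <- QualityLabels(
        cellIds,
        ifelse(classes %in% c("high", "deceptive"), "HIGH", "LOW"),
        ifelse(classes == "high", "none", classes))

    list(counts = CellCounts(counts, erccPrefix = "ERCC-"),
         stats = AlignmentStats(stats),
         geneSets = GeneSetList(sets),
         labels = labels, params = p)
}

#' Simulate a multi-cell-type feature table
#'
#' Builds a cell x feature table in which a small number of designated
#' features carry a large between-type mean shift while the remaining
#' features are type-independent standard normal noise — the structure the
#' loading-quartile feature filter is designed to act on.
#'
#' @param nCells Total cells, split evenly over the types.
#' @param nTypes Number of cell types.
#' @param nFeatures Total number of features.
#' @param nSeparating Number of planted type-separating features.
#' @param shift Between-type mean shift (in noise SDs) of the planted
#'   features.
#' @param seed Integer seed.
#' @return List with \code{features} (\linkS4class{CellFeatures}),
#'   \code{separating} (names of the planted features) and \code{type}
#'   (per-cell type id).
#' @export
simulateTypeFeatures <- function(nCells = 120, nTypes = 3, nFeatures = 20,
                                 nSeparating = 2, shift = 6, seed = 1L) {
    stopifnot(nSeparating < nFeatures, nTypes >= 2)
    withr::with_seed(as.integer(seed), {
        type <- rep_len(seq_len(nTypes), nCells)
        v <- matrix(stats::rnorm(nCells * nFeatures), nCells, nFeatures)
        sep <- sample.int(nFeatures, nSeparating)
        # all planted features share one between-type contrast, so they are
        # strongly correlated and the type separation dominates PC1 — the
        # structure the loading filter is designed to recognize
        contr <- stats::contr.poly(nTypes)[, 1]
        offsets <- matrix(shift * contr, nTypes, nSeparating)
        v[, sep] <- v[, sep] + offsets[type, , drop = FALSE]
        dimnames(v) <- list(sprintf("cell_%03d", seq_len(nCells)),
                            sprintf("feature_%02d", seq_len(nFeatures)))
        list(features = CellFeatures(v, kind = "technical"),
             separating = colnames(v)[sort(sep)],
             type = setNames(type, rownames(v)))
    })
}
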