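# The end-to-end differential expression pipeline: fit on training cells,
# predict the contrast for every cell, select a neighborhood per gene on the
# training half, and test it by pseudobulk aggregation of the held-out half.

#' Pipeline configuration
#'
#' Collects all tunable knobs of [runDePipeline()] with their defaults:
#' 30 latent dimensions, a 50\% test fraction, 100 random directions,
#' neighborhoods of at least 10 cells, z-score selection, normed-sum size
#' factors, the negative-binomial LRT on pseudobulk counts, and a nominal
#' FDR of 10\%.
#'
#' @param nEmbedding latent dimension P.
#' @param testFraction fraction of cells held out for testing (0 disables
#'   splitting: selection and testing reuse the same cells, which inflates
#'   false positives and is offered only for diagnostics).
#' @param nDirections number of random scan directions.
#' @param minCells minimum neighborhood size.
#' @param selectionProcedure \code{"zscore"} or \code{"contrast"}.
#' @param sizeFactorMethod only \code{"normed_sum"} is implemented.
#' @param testMethod \code{"nb_lrt"} (needs raw counts) or \code{"lm"}.
#' @param nominalFdr nominal FDR for reporting.
#' @param lambdaAlign optional alignment ridge weight.
#' @param pseudoCount pseudo-count of the shifted-log transform.
#' @param seed integer seed governing the split and the scan directions.
#' @return validated named list.
#' @export
lemurDeConfig <- function(nEmbedding = 30L, testFraction = 0.5,
                          nDirections = 100L, minCells = 10L,
                          selectionProcedure = c("zscore", "contrast"),
                          sizeFactorMethod = "normed_sum",
                          testMethod = c("nb_lrt", "lm"),
                          nominalFdr = 0.1, lambdaAlign = NULL,
                          pseudoCount = 1, seed = 1L) {
    selectionProcedure <- match.arg(selectionProcedure)
    testMethod <- match.arg(testMethod)
    stopifnot(nEmbedding >= 1, testFraction >= 0, testFraction <= 0.95,
              nDirections >= 1, minCells >= 2, nominalFdr > 0,
              nominalFdr < 1, pseudoCount > 0,
              identical(sizeFactorMethod, "normed_sum"))
    list(nEmbedding = as.integer(nEmbedding), testFraction = testFraction,
         nDirections = as.integer(nDirections), minCells = as.integer(minCells),
         selectionProcedure = selectionProcedure,
         sizeFactorMethod = sizeFactorMethod, testMethod = testMethod,
         nominalFdr = nominalFdr, lambdaAlign = lambdaAlign,
         pseudoCount = pseudoCount, seed = as.integer(seed))
}

#' Run the full neighborhood-based differential expression pipeline
#'
#' Fit (training cells) -> optional alignment -> per-cell predicted
#' differences for the contrast (all cells) -> one neighborhood per gene
#' (training cells) -> pseudobulk aggregation and test on held-out cells
#' only -> BH adjustment across genes. Genes without a neighborhood (constant
#' predicted difference) get NA p-values and are excluded from the
#' adjustment.
#'
#' @param object matrix or [SingleCellExperiment-class] with counts and/or
#'   logcounts; per-cell metadata must contain the sample column.
#' @param design formula or explicit design matrix (see [fitLemur()]).
#' @param rowA,rowB numeric design rows of the contrast, or NULL to build
#'   them from \code{newdataA}/\code{newdataB} via [designRowFor()].
#' @param newdataA,newdataB one-row data.frames of covariate values.
#' @param sampleCol name of the replicate/sample column in the cell metadata.
#' @param matchingSets optional matching sets for [alignWithSets()].
#' @param config a [lemurDeConfig()] list.
#' @param label contrast label.
#' @param cellMeta optional metadata when \code{object} is a matrix.
#' @param verbose emit progress messages.
#' @return a [LemurDEResult-class].
#' @export
runDePipeline <- function(object, design, rowA = NULL, rowB = NULL,
                          newdataA = NULL, newdataB = NULL,
                          sampleCol = "sample_id", matchingSets = NULL,
                          config = lemurDeConfig(), label = "B vs A",
                          cellMeta = NULL, verbose = FALSE) {
    t0 <- proc.time()[["elapsed"]]
    fit <- fitLemur(object, design, nEmbedding = config$nEmbedding,
                    testFraction = config$testFraction, seed = config$seed,
                    pseudo = config$pseudoCount, cellMeta = cellMeta,
                    verbose = verbose)
    .msg(verbose, sprintf("fit: %d genes x %d cells, %.1fs", nrow(fit),
                          ncol(fit), proc.time()[["elapsed"]] - t0))
    if (!is.null(matchingSets))
        fit <- alignWithSets(fit, matchingSets, lambda = config$lambdaAlign,
                             verbose = verbose)
    if (is.null(rowA)) rowA <- designRowFor(fit, newdataA)
    if (is.null(rowB)) rowB <- designRowFor(fit, newdataB)

    delta <- computeDelta(fit, rowA, rowB, label = label)
    Z <- latentEmbedding(fit)
    train <- which(!testMask(fit))
    test <- which(testMask(fit))
    splitting <- length(test) > 0
    if (!splitting) {
        warning("testFraction is 0: neighborhoods are tested on the cells ",
                "used to select them; p-values carry post-selection bias")
        test <- train
    }

    directions <- sampleDirections(fit@latentDim, config$nDirections,
                                   seed = config$seed + 1L)
    sel <- selectNeighborhoods(delta[, train, drop = FALSE],
                               Z[, train, drop = FALSE], directions,
                               minCells = config$minCells,
                               procedure = config$selectionProcedure)
    .msg(verbose, sprintf("neighborhoods selected, %.1fs",
                          proc.time()[["elapsed"]] - t0))

    haveCounts <- "counts" %in% assayNames(fit)
    testMethod <- config$testMethod
    if (testMethod == "nb_lrt" && !haveCounts) {
        warning("no raw counts available; falling back to the linear-model ",
                "test on transformed values")
        testMethod <- "lm"
    }
    meta <- colData(fit)
    if (!sampleCol %in% colnames(meta))
        stop("cell metadata lacks the sample column '", sampleCol, "'")
    sid <- as.factor(meta[[sampleCol]])
    Ktot <- ncol(fit@design)

    # sample-level design: average of member cells' design rows
    sampleLevels <- levels(sid)
    Xs <- t(vapply(sampleLevels, function(l)
        colMeans(fit@design[sid == l, , drop = FALSE]), numeric(Ktot)))
    cvec <- as.numeric(rowB) - as.numeric(rowA)
    if (all(cvec == 0))
        warning("contrast rows are identical; all predicted differences are 0")

    sidTest <- sid[test]
    idxBySample <- lapply(sampleLevels, function(l) which(sidTest == l))
    names(idxBySample) <- sampleLevels
    if (haveCounts) {
        ctest <- as.matrix(assay(fit, "counts"))[, test, drop = FALSE]
        totals <- colSums(ctest)
    } else {
        vtest <- .valuesMatrix(fit)[, test, drop = FALSE]
    }
    Ztest <- Z[, test, drop = FALSE]

    G <- nrow(fit)
    stats <- sel$stats
    lfc <- pval <- rep(NA_real_, G)
    nCells <- rep(NA_integer_, G)
    pois <- rep(FALSE, G)
    nbhList <- vector("list", G)
    names(nbhList) <- rownames(fit)
    minSamples <- ncol(Xs) + 1L
    nbCases <- list()
    nbGenes <- integer(0)

    for (g in seq_len(G)) {
        if (is.na(stats$end[g])) next
        v <- sel$directions[, g]
        memTest <- neighborhoodMembers(v, stats$end[g], stats$threshold[g],
                                       Ztest)
        memAll <- neighborhoodMembers(v, stats$end[g], stats$threshold[g], Z)
        nCells[g] <- sum(memAll)
        nbhList[[g]] <- list(direction = v, end = stats$end[g],
                             threshold = stats$threshold[g],
                             cells = colnames(fit)[memAll])
        ns <- vapply(idxBySample, function(ix) sum(memTest[ix]), integer(1))
        used <- which(ns > 0)
        if (length(used) < minSamples) next
        Xu <- Xs[used, , drop = FALSE]
        if (qr(Xu)$rank < ncol(Xu)) next
        if (testMethod == "nb_lrt") {
            y <- vapply(used, function(s) {
                ix <- idxBySample[[s]]
                sum(ctest[g, ix[memTest[ix]]])
            }, numeric(1))
            tot <- vapply(used, function(s) {
                ix <- idxBySample[[s]]
                sum(totals[ix[memTest[ix]]])
            }, numeric(1))
            cd <- .contrastDesign(Xu, cvec)
            nbCases[[length(nbCases) + 1L]] <-
                list(y = y, Xfull = cd$full, Xred = cd$reduced,
                     offsets = log(tot / mean(tot)))
            nbGenes <- c(nbGenes, g)
        } else {
            y <- vapply(used, function(s) {
                ix <- idxBySample[[s]]
                mean(vtest[g, ix[memTest[ix]]])
            }, numeric(1))
            if (length(used) <= ncol(Xu)) next
            r <- lmTest(matrix(y, nrow = 1), Xu, cvec)
            lfc[g] <- r$lfc[1]; pval[g] <- r$pval[1]
        }
    }
    if (length(nbCases) > 0) {
        resNb <- .nbLrtMany(nbCases)
        lfc[nbGenes] <- resNb[, "lfc"]
        pval[nbGenes] <- resNb[, "pval"]
        pois[nbGenes] <- resNb[, "poisson"] == 1
    }
    adj <- bhAdjust(pval)
    .msg(verbose, sprintf("testing done, %.1fs",
                          proc.time()[["elapsed"]] - t0))

    tab <- DataFrame(gene = rownames(fit), lfc = lfc, pval = pval,
                     adjPval = adj, nCells = nCells,
                     selectionScore = stats$score, end = stats$end,
                     threshold = stats$threshold,
                     poissonFallback = pois, row.names = rownames(fit))
    cfg <- config
    cfg$splitting <- splitting
    cfg$testMethodUsed <- testMethod
    new("LemurDEResult", table = tab, neighborhoods = nbhList,
        contrast = list(rowA = as.numeric(rowA), rowB = as.numeric(rowB),
                        label = label),
        config = cfg, delta = delta)
}
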