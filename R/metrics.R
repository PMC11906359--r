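# Evaluation metrics: k-NN mixing, adjusted Rand index, FDP/TPR, group
# labeling for multi-test methods, and L2 prediction error.

#' k-nearest-neighbor mixing score
#'
#' For each scored cell, the number of its k nearest Euclidean neighbors in
#' the embedding that share its condition label, averaged over scored cells.
#' With a \code{testMask}, held-out cells are scored against training cells
#' only; otherwise every cell is scored against all other cells. For a
#' balanced two-condition dataset in which conditions are fully mixed the
#' ideal value is k/2; a value near k signals separation by condition.
#'
#' @param embedding P x C matrix of latent coordinates.
#' @param labels length-C condition labels.
#' @param k number of neighbors (default 20).
#' @param testMask optional logical length-C vector; TRUE cells are scored,
#'   FALSE cells serve as the reference set.
#' @return mean score in [0, k].
#' @export
knnMixing <- function(embedding, labels, k = 20L, testMask = NULL) {
    C <- ncol(embedding)
    labels <- as.factor(labels)
    stopifnot(length(labels) == C, k >= 1)
    if (is.null(testMask)) {
        scored <- seq_len(C); ref <- seq_len(C); excludeSelf <- TRUE
    } else {
        stopifnot(length(testMask) == C)
        scored <- which(testMask); ref <- which(!testMask)
        excludeSelf <- FALSE
    }
    if (k >= length(ref)) stop("k must be smaller than the reference set")
    Er <- embedding[, ref, drop = FALSE]
    Es <- embedding[, scored, drop = FALSE]
    qr2 <- colSums(Er^2)
    qs2 <- colSums(Es^2)
    D <- outer(qs2, qr2, "+") - 2 * crossprod(Es, Er)
    sameCount <- vapply(seq_along(scored), function(i) {
        d <- D[i, ]
        if (excludeSelf) d[ref == scored[i]] <- Inf
        nn <- order(d)[seq_len(k)]
        sum(labels[ref[nn]] == labels[scored[i]])
    }, numeric(1))
    mean(sameCount)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement of two labelings under the permutation model
#' (delegates to \code{mclust::adjustedRandIndex}).
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @return a number <= 1; 1 for identical partitions, ~0 for independent
#'   ones.
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
    if (length(labelsA) != length(labelsB))
        stop("labelings must have equal length")
    mclust::adjustedRandIndex(labelsA, labelsB)
}

#' Gene-level false discovery proportion and true positive rate
#'
#' Calls are genes with adjusted p-value below the nominal level. FDP is the
#' fraction of false calls among calls (0 when nothing is called); TPR is
#' the fraction of truly differential genes that are called.
#'
#' @param result a [LemurDEResult-class], or a named numeric vector of
#'   adjusted p-values.
#' @param isDe logical ground-truth flags, named by gene or aligned by
#'   position.
#' @param nominal nominal FDR threshold (default 0.1).
#' @return named numeric vector \code{c(fdp, tpr)}.
#' @export
fdpTpr <- function(result, isDe, nominal = 0.1) {
    adj <- if (is(result, "LemurDEResult")) {
        setNames(deTable(result)$adjPval, deTable(result)$gene)
    } else result
    if (!is.null(names(adj)) && !is.null(names(isDe)))
        isDe <- isDe[names(adj)]
    stopifnot(length(adj) == length(isDe))
    called <- !is.na(adj) & adj < nominal
    fdp <- sum(called & !isDe) / max(1, sum(called))
    tpr <- sum(called & isDe) / max(1, sum(isDe))
    c(fdp = fdp, tpr = tpr)
}

#' Label cell groups against a set of changed cells
#'
#' For methods that test many cell groups per gene: a group is positive if
#' more than 60\% of its cells changed and at least \code{minChanged} cells
#' changed; if no group qualifies, the group with the largest changed
#' fraction is positive. A group is negative below 10\% changed cells;
#' anything between is indeterminate and ignored in FDP/TPR accounting.
#'
#' @param groups list of cell-index vectors.
#' @param changedCells indices of truly changed cells.
#' @param minChanged minimum changed-cell count for a positive label.
#' @return character vector (\code{"positive"}, \code{"negative"},
#'   \code{"indeterminate"}) per group.
#' @export
labelCellGroups <- function(groups, changedCells, minChanged = 10L) {
    stopifnot(length(groups) > 0, all(lengths(groups) > 0))
    nChanged <- vapply(groups, function(g) sum(g %in% changedCells),
                       numeric(1))
    frac <- nChanged / lengths(groups)
    lab <- rep("indeterminate", length(groups))
    lab[frac > 0.6 & nChanged >= minChanged] <- "positive"
    lab[frac < 0.1] <- "negative"
    if (!any(lab == "positive")) lab[which.max(frac)] <- "positive"
    lab
}

#' L2 prediction-error metrics
#'
#' The L2 distance between the mean predicted and the mean observed
#' expression vectors, overall and per cell type, and the same for the
#' per-gene standard deviations.
#'
#' @param pred,obs G x n matrices on a shared gene set (columns are cells;
#'   the two matrices may cover different cells of the same populations).
#' @param cellTypesPred,cellTypesObs cell-type labels for the columns of
#'   each matrix; defaults compare whole matrices only.
#' @return list with \code{meanOverall}, \code{sdOverall} and, when labels
#'   are given, named vectors \code{meanPerType}, \code{sdPerType}.
#' @export
predictionL2Metrics <- function(pred, obs, cellTypesPred = NULL,
                                cellTypesObs = NULL) {
    stopifnot(nrow(pred) == nrow(obs))
    l2 <- function(x, y) sqrt(sum((x - y)^2))
    rowSd <- function(m) {
        mu <- rowMeans(m)
        sqrt(pmax(0, rowMeans(m^2) - mu^2) * ncol(m) / max(1, ncol(m) - 1))
    }
    out <- list(meanOverall = l2(rowMeans(pred), rowMeans(obs)),
                sdOverall = l2(rowSd(pred), rowSd(obs)))
    if (!is.null(cellTypesPred)) {
        stopifnot(!is.null(cellTypesObs))
        types <- sort(unique(c(as.character(cellTypesPred),
                               as.character(cellTypesObs))))
        mp <- sp <- setNames(rep(NA_real_, length(types)), types)
        for (tp in types) {
            ip <- which(cellTypesPred == tp); io <- which(cellTypesObs == tp)
            if (length(ip) == 0 || length(io) == 0)
                stop("cell type '", tp, "' is empty in one of the matrices")
            mp[tp] <- l2(rowMeans(pred[, ip, drop = FALSE]),
                         rowMeans(obs[, io, drop = FALSE]))
            sp[tp] <- l2(rowSd(pred[, ip, drop = FALSE]),
                         rowSd(obs[, io, drop = FALSE]))
        }
        out$meanPerType <- mp
        out$sdPerType <- sp
    }
    out
}
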