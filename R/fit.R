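# The multi-condition PCA fit: offset regression, base subspace, per-condition
# tangents, and the cell embedding.

#' Linear offset coefficients
#'
#' Ordinary least squares of the values matrix on the design:
#' \eqn{\Gamma = argmin |Y - \Gamma X^T|_F^2}. With an intercept-only design
#' this reduces to the row-wise means of Y.
#'
#' @param Y numeric G x C matrix.
#' @param X numeric C x K design matrix of full column rank.
#' @return G x K coefficient matrix.
#' @export
fitOffset <- function(Y, X) {
    X <- as.matrix(X)
    qrd <- qr(X)
    if (qrd$rank < ncol(X))
        stop("design matrix is rank deficient")
    gamma <- t(qr.coef(qrd, t(Y)))
    dimnames(gamma) <- list(rownames(Y), colnames(X))
    gamma
}

# Resolve a design specification (formula or matrix) against cell metadata.
.resolveDesign <- function(design, meta, C) {
    if (inherits(design, "formula")) {
        X <- model.matrix(design, data = as.data.frame(meta))
        spec <- design
    } else {
        X <- as.matrix(design)
        spec <- NULL
    }
    if (nrow(X) != C)
        stop("design has ", nrow(X), " rows but the data has ", C, " cells")
    if (qr(X)$rank < ncol(X))
        stop("design matrix is rank deficient; check for confounded covariates")
    list(X = X, spec = spec)
}

#' Fit the multi-condition latent embedding model
#'
#' Fits, on the training cells, (1) the linear offset \eqn{\Gamma} by least
#' squares, (2) the base subspace \eqn{o} as the top-P left singular subspace
#' of the pooled offset residuals, (3) one P-dimensional PCA subspace per
#' condition (distinct design row), its Grassmann logarithm at \eqn{o}, and
#' the tangent coefficients \eqn{B} by cell-count-weighted least squares
#' across the distinct design rows. The embedding \eqn{Z} of every cell
#' (training and held-out) is the orthogonal projection of its offset
#' residual onto its condition's subspace. Alignment parameters are
#' initialized to the identity (see [alignWithSets()]).
#'
#' Conditions with fewer than \code{2 * nEmbedding} training cells contribute
#' a tangent shrunk toward the base point proportionally to their cell count
#' (a condition with fewer than \code{nEmbedding} cells contributes the zero
#' tangent); a warning reports how many conditions were shrunk.
#'
#' @param object a [SingleCellExperiment-class]/SummarizedExperiment with a
#'   \code{counts} and/or \code{logcounts} assay, or a numeric matrix of
#'   variance-stabilized values (genes x cells).
#' @param design model formula evaluated on \code{colData(object)} (or
#'   \code{cellMeta}), or an explicit numeric C x K design matrix.
#' @param nEmbedding latent dimension P (default 30).
#' @param testFraction fraction of cells held out from all parameter
#'   estimation (default 0.5); set to 0 to train on every cell.
#' @param seed integer seed fixing the train/test split.
#' @param pseudo pseudo-count of the shifted-log transform applied when only
#'   counts are present (default 1).
#' @param cellMeta optional per-cell data.frame when \code{object} is a bare
#'   matrix.
#' @param verbose emit progress messages.
#' @return a [LemurFit-class].
#' @examples
#' y <- matrix(rnorm(50 * 40), 50, 40)
#' fit <- fitLemur(y, design = ~1, nEmbedding = 5, testFraction = 0, seed = 1)
#' dim(latentEmbedding(fit))
#' @export
fitLemur <- function(object, design = ~1, nEmbedding = 30L,
                     testFraction = 0.5, seed = 1L, pseudo = 1,
                     cellMeta = NULL, verbose = FALSE) {
    nEmbedding <- as.integer(nEmbedding)
    seed <- as.integer(seed)
    stopifnot(nEmbedding >= 1L, testFraction >= 0, testFraction <= 0.95)

    if (is(object, "SummarizedExperiment")) {
        sce <- as(object, "SingleCellExperiment")
        meta <- as.data.frame(colData(sce))
    } else {
        m <- as.matrix(object)
        if (is.null(colnames(m)))
            colnames(m) <- paste0("cell_", seq_len(ncol(m)))
        if (is.null(rownames(m)))
            rownames(m) <- paste0("gene_", seq_len(nrow(m)))
        meta <- if (is.null(cellMeta)) data.frame(row.names = colnames(m))
                else cellMeta
        looksLikeCounts <- all(m >= 0) && max(abs(m - round(m))) == 0
        sce <- if (looksLikeCounts)
            SingleCellExperiment(assays = list(counts = m),
                                 colData = DataFrame(meta))
        else
            SingleCellExperiment(assays = list(logcounts = m),
                                 colData = DataFrame(meta))
    }
    if (!"logcounts" %in% assayNames(sce)) {
        if (!"counts" %in% assayNames(sce))
            stop("object must carry a 'counts' or 'logcounts' assay")
        cnts <- assay(sce, "counts")
        sf <- sizeFactorsNormedSum(cnts)
        SummarizedExperiment::assay(sce, "logcounts") <-
            shiftedLogTransform(cnts, sf, pseudo)
    }
    Y <- as.matrix(assay(sce, "logcounts"))
    G <- nrow(Y); C <- ncol(Y)
    if (nEmbedding >= min(G, C))
        stop("latent dimension must be smaller than min(genes, cells)")

    des <- .resolveDesign(design, colData(sce), C)
    X <- des$X; K <- ncol(X)

    set.seed(seed)
    testMask <- rep(FALSE, C)
    nTest <- floor(testFraction * C)
    if (nTest > 0) testMask[sample.int(C, nTest)] <- TRUE
    train <- which(!testMask)
    if (length(train) <= nEmbedding)
        stop("too few training cells for the requested latent dimension")

    core <- .fitMultiConditionPca(Y[, train, drop = FALSE],
                                  X[train, , drop = FALSE],
                                  nEmbedding, verbose = verbose)

    fit <- new("LemurFit", sce,
               basePoint = core$basePoint,
               coefB = core$coefB,
               gamma = core$gamma,
               alignW = array(0, dim = c(nEmbedding, nEmbedding, K)),
               alignW0 = matrix(0, nEmbedding, K),
               embedding = matrix(0, nEmbedding, C,
                                  dimnames = list(NULL, colnames(Y))),
               design = X,
               designSpec = des$spec,
               latentDim = nEmbedding,
               lambdaAlign = NA_real_,
               testMask = testMask,
               seedUsed = seed)
    fit@embedding <- embedCells(fit, Y, X)
    fit
}

# Core closed-form two-stage estimator, operating on training data only.
.fitMultiConditionPca <- function(Y, X, P, verbose = FALSE) {
    G <- nrow(Y); K <- ncol(X)
    gamma <- fitOffset(Y, X)
    E <- Y - tcrossprod(gamma, X)

    sv <- svd(E, nu = P, nv = 0)
    o <- GrassmannPoint(.fixSigns(sv$u))

    rows <- .uniqueRows(X)
    J <- nrow(rows$Xd)
    nShrunk <- 0L
    Tmat <- matrix(0, G * P, J)
    for (j in seq_len(J)) {
        idx <- which(rows$group == j)
        nj <- length(idx)
        if (nj < P) { nShrunk <- nShrunk + 1L; next }  # zero tangent
        Ej <- E[, idx, drop = FALSE]
        svj <- svd(Ej, nu = P, nv = 0)
        if (sum(svj$d > svj$d[1] * 1e-10) < P) {
            # residuals of this condition do not span P directions; complete
            # the basis with base-point directions (zero extra tangent there)
            qj <- .completeBasis(svj$u, svj$d, o@basis, P)
        } else qj <- svj$u
        tj <- tryCatch(grassmannLog(o, GrassmannPoint(.fixSigns(qj)))@coords,
                       error = function(e) { matrix(0, G, P) })
        if (nj < 2 * P) {
            tj <- tj * (nj / (2 * P))
            nShrunk <- nShrunk + 1L
        }
        Tmat[, j] <- as.vector(tj)
    }
    if (nShrunk > 0)
        warning(nShrunk, " condition(s) had fewer than 2 * P training cells; ",
                "their tangents were shrunk toward the base subspace")

    if (qr(rows$Xd)$rank < K)
        stop("distinct design rows do not span the design space; ",
             "the tangent regression is unidentifiable")
    coefFlat <- .weightedLsMinNorm(Tmat, rows$Xd, rows$counts)  # (G*P) x K
    coefB <- array(coefFlat, dim = c(G, P, K))
    ob <- o@basis
    for (k in seq_len(K)) {
        slice <- coefB[, , k]
        coefB[, , k] <- slice - ob %*% crossprod(ob, slice)
    }
    .msg(verbose, "fitted ", J, " condition subspace(s) at P = ", P)
    list(basePoint = o, coefB = coefB, gamma = gamma)
}

# Pad a rank-deficient per-condition basis with base-point columns orthogonal
# to the leading directions, so the Grassmann log stays well defined.
.completeBasis <- function(u, d, obasis, P) {
    keep <- which(d > max(d[1], 1e-300) * 1e-10)
    ulead <- u[, keep, drop = FALSE]
    cand <- obasis - ulead %*% crossprod(ulead, obasis)
    qc <- qr(cand)
    extra <- qr.Q(qc)[, seq_len(P - length(keep)), drop = FALSE]
    cbind(ulead, extra)
}

#' Embed cells into the fitted latent space
#'
#' Projects cells onto their condition's subspace and applies the inverse
#' alignment: \eqn{Z'_{:c} = S^{-1}(x_c) (R(x_c)^T (Y_{:c} - \gamma(x_c)) -
#' s_0(x_c))}. With identity alignment this is the plain orthogonal
#' projection; re-embedding training cells reproduces the stored embedding.
#'
#' @param fit a [LemurFit-class].
#' @param Y numeric G x n matrix of variance-stabilized values.
#' @param X numeric n x K design matrix (or length-K vector for one row).
#' @return P x n matrix of latent coordinates.
#' @export
embedCells <- function(fit, Y, X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = ncol(Y), ncol = length(X),
                                     byrow = TRUE)
    stopifnot(nrow(Y) == nrow(fit), nrow(X) == ncol(Y),
              ncol(X) == ncol(fit@design))
    rows <- .uniqueRows(X)
    Z <- matrix(0, fit@latentDim, ncol(Y), dimnames = list(NULL, colnames(Y)))
    for (j in seq_len(nrow(rows$Xd))) {
        x <- rows$Xd[j, ]
        idx <- which(rows$group == j)
        R <- .subspaceAt(fit@basePoint, fit@coefB, x)
        al <- .alignAt(fit@alignW, fit@alignW0, x)
        zraw <- crossprod(R, Y[, idx, drop = FALSE] - .gammaAt(fit@gamma, x))
        Z[, idx] <- solve(al$S, zraw - al$s0)
    }
    Z
}

#' Fraction of variance explained by the fitted model
#'
#' \eqn{1 - |Y - \hat Y|_F^2 / |Y - rowMeans(Y)|_F^2}, where \eqn{\hat Y} is
#' the model reconstruction of each cell in its own condition.
#'
#' @param fit a [LemurFit-class].
#' @param Y optional G x n values matrix (defaults to the fitted data).
#' @param X optional matching design matrix.
#' @param cells which stored cells to evaluate when Y is missing:
#'   \code{"all"}, \code{"train"} or \code{"test"}.
#' @return a number in \eqn{[0, 1]} (can be negative for a misspecified fit
#'   on new data).
#' @export
varianceExplained <- function(fit, Y = NULL, X = NULL,
                              cells = c("all", "train", "test")) {
    cells <- match.arg(cells)
    if (is.null(Y)) {
        keep <- switch(cells, all = rep(TRUE, ncol(fit)),
                       train = !fit@testMask, test = fit@testMask)
        Y <- .valuesMatrix(fit)[, keep, drop = FALSE]
        X <- fit@design[keep, , drop = FALSE]
        Z <- fit@embedding[, keep, drop = FALSE]
    } else {
        stopifnot(!is.null(X))
        Z <- embedCells(fit, Y, X)
    }
    Yhat <- .reconstruct(fit, Z, X)
    ssTot <- sum((Y - rowMeans(Y))^2)
    if (ssTot == 0) stop("Y is constant; variance explained is undefined")
    1 - sum((Y - Yhat)^2) / ssTot
}

# Reconstruction R(x) (S(x) Z' + s0(x)) + gamma(x) for stored-style inputs.
.reconstruct <- function(fit, Zprime, X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = ncol(Zprime),
                                     ncol = length(X), byrow = TRUE)
    rows <- .uniqueRows(X)
    Yhat <- matrix(0, nrow(fit), ncol(Zprime))
    for (j in seq_len(nrow(rows$Xd))) {
        x <- rows$Xd[j, ]
        idx <- which(rows$group == j)
        R <- .subspaceAt(fit@basePoint, fit@coefB, x)
        al <- .alignAt(fit@alignW, fit@alignW0, x)
        Yhat[, idx] <- R %*% (al$S %*% Zprime[, idx, drop = FALSE] + al$s0) +
            .gammaAt(fit@gamma, x)
    }
    Yhat
}
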