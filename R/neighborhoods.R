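# Neighborhood selection on training cells and pseudobulk testing on held-out
# cells. A neighborhood is always a half-space of the latent embedding:
# membership is a threshold on one linear projection, which makes it convex
# and cheaply transferable to unseen cells.

#' Random unit directions in latent space
#'
#' i.i.d. uniform draws on the unit sphere in \eqn{R^P} (normalized Gaussian
#' vectors), shared across genes by the selection scan.
#'
#' @param P latent dimension.
#' @param nDir number of directions.
#' @param seed integer seed.
#' @return P x nDir matrix of unit columns.
#' @export
sampleDirections <- function(P, nDir, seed = 1L) {
    stopifnot(nDir >= 1)
    set.seed(as.integer(seed))
    v <- matrix(rnorm(P * nDir), P, nDir)
    sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' Select one latent-space neighborhood per gene
#'
#' For each direction \eqn{v} and each end (high/low), training cells are
#' ordered by the projection \eqn{t_c = v \cdot z'_c} and every prefix with at
#' least \code{minCells} members is scored
#' \eqn{z(N) = |\sum_{c \in N} \delta_c| / (sd(\delta) \sqrt{|N|})}. The
#' best-scoring (direction, end, threshold) triple defines the gene's
#' neighborhood; membership of any cell follows by thresholding its own
#' projection. Genes with constant \eqn{\delta} get no neighborhood.
#'
#' @param delta numeric G x Ctrain matrix of per-cell predicted differences
#'   (training cells).
#' @param Zprime numeric P x Ctrain latent coordinates of the same cells.
#' @param directions P x nDir matrix of candidate unit directions
#'   ([sampleDirections()]); ignored for \code{procedure = "contrast"}.
#' @param minCells smallest admissible neighborhood (default 10).
#' @param procedure \code{"zscore"} scans the shared random directions;
#'   \code{"contrast"} scans, per gene, the single direction
#'   \eqn{v_g \propto \sum_c \delta_{gc} z'_c} (the covariance of the
#'   predicted change with latent position).
#' @return list with \code{stats} (a [S4Vectors::DataFrame]: score, end,
#'   threshold, size per gene; NA rows for genes without signal) and
#'   \code{directions}, the P x G matrix of selected unit directions.
#' @export
selectNeighborhoods <- function(delta, Zprime, directions = NULL,
                                minCells = 10,
                                procedure = c("zscore", "contrast")) {
    procedure <- match.arg(procedure)
    G <- nrow(delta); Ctr <- ncol(delta)
    stopifnot(ncol(Zprime) == Ctr)
    if (Ctr < minCells) stop("fewer training cells than minCells")
    mu <- rowMeans(delta)
    sdg <- sqrt(pmax(0, (rowSums(delta^2) - Ctr * mu^2) / (Ctr - 1)))
    valid <- sdg > 0

    if (procedure == "contrast") {
        V <- Zprime %*% t(delta)                   # P x G
        nrm <- sqrt(colSums(V^2))
        ok <- valid & nrm > 0
        V[, ok] <- sweep(V[, ok, drop = FALSE], 2, nrm[ok], "/")
        res <- .scanPerGeneDirections(delta, Zprime, V, ok, sdg, minCells)
        return(list(stats = res, directions = V))
    }

    stopifnot(!is.null(directions), nrow(directions) == nrow(Zprime))
    nDir <- ncol(directions)
    proj <- crossprod(directions, Zprime)          # nDir x Ctr
    sizes <- seq.int(minCells, Ctr)
    sq <- sqrt(sizes)
    bestScore <- rep(-Inf, G); bestDir <- rep(NA_integer_, G)
    bestEnd <- rep(NA_character_, G); bestSize <- rep(NA_integer_, G)
    invSd <- ifelse(valid, 1 / sdg, 0)

    for (d in seq_len(nDir)) {
        ord <- order(proj[d, ], decreasing = TRUE)
        CS <- .rowCumsum(delta[, ord, drop = FALSE])
        tot <- CS[, Ctr]
        high <- abs(CS[, sizes, drop = FALSE])
        lowIdx <- Ctr - sizes
        low <- abs(tot - cbind(CS[, lowIdx[lowIdx > 0], drop = FALSE],
                               if (any(lowIdx == 0)) 0))
        comb <- cbind(high, low) * invSd           # recycle rows
        comb <- sweep(comb, 2, c(sq, sq), "/")
        jmax <- max.col(comb, ties.method = "first")
        smax <- comb[cbind(seq_len(G), jmax)]
        upd <- valid & smax > bestScore
        if (any(upd)) {
            nS <- length(sizes)
            isHigh <- jmax[upd] <= nS
            bestScore[upd] <- smax[upd]
            bestDir[upd] <- d
            bestEnd[upd] <- ifelse(isHigh, "high", "low")
            bestSize[upd] <- sizes[ifelse(isHigh, jmax[upd], jmax[upd] - nS)]
        }
    }

    thr <- rep(NA_real_, G)
    for (d in unique(bestDir[!is.na(bestDir)])) {
        srt <- sort(proj[d, ], decreasing = TRUE)
        g <- which(!is.na(bestDir) & bestDir == d)
        hi <- g[bestEnd[g] == "high"]
        lo <- g[bestEnd[g] == "low"]
        thr[hi] <- srt[bestSize[hi]]
        thr[lo] <- srt[Ctr - bestSize[lo] + 1L]
    }
    dirMat <- matrix(NA_real_, nrow(Zprime), G)
    dirMat[, !is.na(bestDir)] <- directions[, bestDir[!is.na(bestDir)]]
    list(stats = DataFrame(score = ifelse(valid, bestScore, NA_real_),
                           dirIdx = bestDir, end = bestEnd,
                           threshold = thr, size = bestSize,
                           row.names = rownames(delta)),
         directions = dirMat)
}

# Per-gene single-direction scan used by the "contrast" procedure.
.scanPerGeneDirections <- function(delta, Zprime, V, ok, sdg, minCells) {
    G <- nrow(delta); Ctr <- ncol(delta)
    score <- thr <- rep(NA_real_, G)
    end <- rep(NA_character_, G); size <- rep(NA_integer_, G)
    sizes <- seq.int(minCells, Ctr); sq <- sqrt(sizes)
    for (g in which(ok)) {
        t <- drop(crossprod(V[, g], Zprime))
        ord <- order(t, decreasing = TRUE)
        cs <- cumsum(delta[g, ord])
        tot <- cs[Ctr]
        zh <- abs(cs[sizes]) / sq
        lowIdx <- Ctr - sizes
        zl <- abs(tot - c(cs[lowIdx[lowIdx > 0]],
                          if (any(lowIdx == 0)) 0)) / sq
        if (max(zh) >= max(zl)) {
            m <- which.max(zh); end[g] <- "high"
            size[g] <- sizes[m]; score[g] <- zh[m] / sdg[g]
            thr[g] <- t[ord][sizes[m]]
        } else {
            m <- which.max(zl); end[g] <- "low"
            size[g] <- sizes[m]; score[g] <- zl[m] / sdg[g]
            thr[g] <- t[ord][Ctr - sizes[m] + 1L]
        }
    }
    DataFrame(score = score, dirIdx = NA_integer_, end = end,
              threshold = thr, size = size, row.names = rownames(delta))
}

#' Neighborhood membership from its defining half-space
#'
#' @param direction length-P unit vector.
#' @param end \code{"high"} or \code{"low"}.
#' @param threshold projection cutoff.
#' @param Zprime P x n latent coordinates to classify.
#' @return logical length-n membership vector.
#' @export
neighborhoodMembers <- function(direction, end, threshold, Zprime) {
    t <- drop(crossprod(direction, Zprime))
    if (end == "high") t >= threshold else t <= threshold
}

#' Pseudobulk aggregation over a cell set
#'
#' Sums raw counts (\code{mode = "sum"}) or averages transformed values
#' (\code{mode = "mean"}) of the member cells per sample. Samples with no
#' member cells are kept as zero columns and flagged via \code{nCells}.
#'
#' @param values G x C matrix (counts or transformed values).
#' @param cells integer or logical index of member cells.
#' @param sampleIds length-C sample labels (coerced to factor; its levels fix
#'   the output columns).
#' @param mode \code{"sum"} or \code{"mean"}.
#' @return list with \code{matrix} (G x S) and \code{nCells} (per-sample
#'   member counts).
#' @export
pseudobulkAggregate <- function(values, cells, sampleIds,
                                mode = c("sum", "mean")) {
    mode <- match.arg(mode)
    sampleIds <- as.factor(sampleIds)
    if (is.logical(cells)) cells <- which(cells)
    if (length(cells) == 0) stop("cells must be non-empty")
    sid <- factor(sampleIds[cells], levels = levels(sampleIds))
    sub <- as.matrix(values)[, cells, drop = FALSE]
    ind <- vapply(levels(sid), function(l) as.numeric(sid == l),
                  numeric(length(cells)))
    if (length(cells) == 1L) ind <- matrix(ind, nrow = 1)
    agg <- sub %*% ind
    n <- as.integer(table(sid))
    if (mode == "mean") {
        agg <- sweep(agg, 2, pmax(n, 1L), "/")
    }
    colnames(agg) <- levels(sid)
    list(matrix = agg, nCells = setNames(n, levels(sid)))
}

# Reparameterize a design so that column 1 carries the contrast coefficient
# c' beta; dropping it gives the reduced model of the LRT.
.contrastDesign <- function(X, contrast) {
    K <- ncol(X)
    stopifnot(length(contrast) == K, any(contrast != 0))
    Qfull <- qr.Q(qr(matrix(contrast, ncol = 1)), complete = TRUE)
    A <- rbind(contrast, t(Qfull[, -1, drop = FALSE]))
    Xstar <- X %*% solve(A)
    list(full = Xstar, reduced = Xstar[, -1, drop = FALSE])
}

# Negative-binomial likelihood-ratio testing with empirical-Bayes moderated
# dispersion.
#
# With only a handful of pseudobulk samples per gene, plain per-gene ML
# dispersion estimates are biased toward zero and make the chi-squared LRT
# anticonservative. Dispersion is therefore estimated from the Cox-Reid
# adjusted profile likelihood (APL) and moderated across genes by weighted
# likelihood: each gene maximizes APL_g + (priorDf / df_g) * mean(APL) over
# the dispersion grid, the small-sample strategy of the standard pseudobulk
# count tools. The dispersion floor is 1e-8.

.nbAlphaGrid <- function() exp(seq(log(1e-8), log(100), length.out = 25L))

# Cached family objects for the grid (construction dominates tiny fits).
.nbFamilies <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- lapply(.nbAlphaGrid(), function(a)
                MASS::negative.binomial(theta = 1 / a))
        cache
    }
})

# Cox-Reid APL of one case at one grid index.
.nbApl <- function(y, X, offsets, gridIdx, etastart = NULL) {
    fam <- .nbFamilies()[[gridIdx]]
    theta <- 1 / .nbAlphaGrid()[gridIdx]
    f <- suppressWarnings(glm.fit(X, y, offset = offsets, family = fam,
                                  etastart = etastart))
    mu <- pmax(f$fitted.values, 1e-10)
    w <- mu / (1 + mu / theta)
    as.numeric(sum(dnbinom(y, size = theta, mu = mu, log = TRUE)) -
        0.5 * determinant(crossprod(X * sqrt(w)),
                          logarithm = TRUE)$modulus)
}

# Argmax over a log-spaced grid, refined by fitting a quadratic in
# log-alpha through the maximum and its neighbours.
.gridArgmax <- function(grid, curve) {
    i <- which.max(curve)
    if (i == 1L || i == length(grid)) return(grid[i])
    x <- log(grid[(i - 1):(i + 1)])
    yv <- curve[(i - 1):(i + 1)]
    denom <- (yv[1] - 2 * yv[2] + yv[3])
    if (!is.finite(denom) || denom >= 0) return(grid[i])
    xhat <- x[2] - 0.5 * (x[3] - x[1]) / 2 * (yv[3] - yv[1]) / denom
    exp(min(max(xhat, x[1]), x[3]))
}

# Run the moderated NB LRT over a list of cases, each a list with elements
# y, Xfull, Xred, offsets. Returns a matrix with columns lfc, pval, poisson.
.nbLrtMany <- function(cases, priorDf = 10) {
    nG <- length(cases)
    out <- matrix(NA_real_, nG, 3,
                  dimnames = list(NULL, c("lfc", "pval", "poisson")))
    if (nG == 0) return(out)
    grid <- .nbAlphaGrid()
    apl <- matrix(NA_real_, nG, length(grid))
    for (g in seq_len(nG)) {
        cs <- cases[[g]]
        if (all(cs$y == 0)) next
        apl[g, ] <- tryCatch({
            # Poisson warm start shared across the dispersion grid
            fp <- suppressWarnings(glm.fit(cs$Xfull, cs$y,
                offset = cs$offsets, family = poisson()))
            eta <- log(pmax(fp$fitted.values, 1e-10))
            vapply(seq_along(grid), function(i)
                .nbApl(cs$y, cs$Xfull, cs$offsets, i, etastart = eta),
                numeric(1))
        }, error = function(e) rep(NA_real_, length(grid)))
    }
    okRows <- rowSums(is.na(apl)) == 0
    meanApl <- if (any(okRows)) colMeans(apl[okRows, , drop = FALSE])
               else rep(0, length(grid))
    # common dispersion across genes (grid argmax refined by a quadratic in
    # log-alpha); per-gene estimates are moderated toward it and never
    # allowed below it -- genes whose few samples happen to scatter tightly
    # would otherwise dominate the false discoveries
    alphaCommon <- .gridArgmax(grid, meanApl)
    for (g in seq_len(nG)) {
        cs <- cases[[g]]
        if (all(cs$y == 0)) { out[g, ] <- c(0, 1, 0); next }
        res <- tryCatch({
            if (!okRows[g]) stop("APL curve failed")
            w <- priorDf / max(1, length(cs$y) - ncol(cs$Xfull))
            alpha <- max(alphaCommon,
                         .gridArgmax(grid, apl[g, ] + w * meanApl))
            fam <- MASS::negative.binomial(theta = 1 / alpha)
            ffull <- suppressWarnings(glm.fit(cs$Xfull, cs$y,
                offset = cs$offsets, family = fam))
            fred <- suppressWarnings(glm.fit(cs$Xred, cs$y,
                offset = cs$offsets, family = fam))
            llf <- sum(dnbinom(cs$y, size = 1 / alpha,
                               mu = pmax(ffull$fitted.values, 1e-10),
                               log = TRUE))
            llr <- sum(dnbinom(cs$y, size = 1 / alpha,
                               mu = pmax(fred$fitted.values, 1e-10),
                               log = TRUE))
            stat <- max(0, 2 * (llf - llr))
            dfTest <- max(1, length(cs$y) - ncol(cs$Xfull)) + priorDf
            c(unname(ffull$coefficients[1]) / log(2),
              stats::pf(stat, 1, dfTest, lower.tail = FALSE), 0)
        }, error = function(e) NULL)
        if (is.null(res) || anyNA(res)) res <- tryCatch({
            ffull <- suppressWarnings(glm.fit(cs$Xfull, cs$y,
                offset = cs$offsets, family = poisson()))
            fred <- suppressWarnings(glm.fit(cs$Xred, cs$y,
                offset = cs$offsets, family = poisson()))
            llf <- sum(dpois(cs$y, pmax(ffull$fitted.values, 1e-10),
                             log = TRUE))
            llr <- sum(dpois(cs$y, pmax(fred$fitted.values, 1e-10),
                             log = TRUE))
            stat <- max(0, 2 * (llf - llr))
            dfTest <- max(1, length(cs$y) - ncol(cs$Xfull)) + priorDf
            c(unname(ffull$coefficients[1]) / log(2),
              stats::pf(stat, 1, dfTest, lower.tail = FALSE), 1)
        }, error = function(e) c(NA_real_, NA_real_, 1))
        out[g, ] <- res
    }
    out
}

#' Pseudobulk negative-binomial likelihood-ratio test
#'
#' Per gene, fits a negative-binomial GLM with log link and offsets under
#' the full design and under the design with the tested contrast removed,
#' and reports the two-sided p-value of the likelihood-ratio statistic
#' against an F(1, df + priorDf) reference. The per-gene dispersion
#' (floored at 1e-8) is estimated from the Cox-Reid adjusted profile
#' likelihood and moderated across genes by weighted likelihood (each
#' gene's profile is augmented with \code{priorDf / df} times the average
#' profile). The moderation and the F reference together remove the
#' downward small-sample bias of plain per-gene maximum likelihood with a
#' chi-squared reference, which is strongly anticonservative with a handful
#' of pseudobulk samples. Genes whose NB fit fails are tested with a
#' Poisson LRT and flagged.
#'
#' @param pseudoCounts G x S matrix of pseudobulk counts.
#' @param sampleDesign S x Ks sample-level design matrix.
#' @param contrast length-Ks numeric contrast vector whose coefficient is
#'   tested against zero (its estimate, divided by log 2, is the reported
#'   log2 fold change).
#' @param offsets length-S offsets on the log scale (log pseudobulk size
#'   factors); default all zero.
#' @param priorDf prior degrees of freedom of the dispersion moderation
#'   (default 10).
#' @return [S4Vectors::DataFrame] with \code{lfc}, \code{pval},
#'   \code{poissonFallback} per gene.
#' @export
nbGlmLrt <- function(pseudoCounts, sampleDesign, contrast,
                     offsets = rep(0, ncol(pseudoCounts)), priorDf = 10) {
    S <- ncol(pseudoCounts)
    sampleDesign <- as.matrix(sampleDesign)
    stopifnot(nrow(sampleDesign) == S, all(is.finite(offsets)))
    if (S < ncol(sampleDesign) + 1)
        stop("need more samples than design columns for the LRT")
    cd <- .contrastDesign(sampleDesign, contrast)
    cases <- lapply(seq_len(nrow(pseudoCounts)), function(g)
        list(y = pseudoCounts[g, ], Xfull = cd$full, Xred = cd$reduced,
             offsets = offsets))
    res <- .nbLrtMany(cases, priorDf = priorDf)
    DataFrame(lfc = unname(res[, 1]), pval = unname(res[, 2]),
              poissonFallback = unname(res[, 3] == 1),
              row.names = rownames(pseudoCounts))
}

#' Pseudobulk linear-model test on transformed values
#'
#' Ordinary least squares of each gene's pseudobulk means on the sample
#' design, with a two-sided t-test on the contrast coefficient. Used when raw
#' counts are unavailable.
#'
#' @param pseudoMeans G x S matrix of per-sample mean transformed values.
#' @param sampleDesign S x Ks design matrix.
#' @param contrast length-Ks contrast vector.
#' @return [S4Vectors::DataFrame] with \code{lfc} (log2 scale) and
#'   \code{pval}.
#' @export
lmTest <- function(pseudoMeans, sampleDesign, contrast) {
    S <- ncol(pseudoMeans)
    X <- as.matrix(sampleDesign)
    if (S <= ncol(X)) stop("need more samples than design columns")
    cd <- .contrastDesign(X, contrast)
    Xs <- cd$full
    qrd <- qr(Xs)
    coefs <- qr.coef(qrd, t(pseudoMeans))            # Ks x G
    fitted <- Xs %*% coefs
    rss <- colSums((t(pseudoMeans) - fitted)^2)
    df <- S - ncol(Xs)
    sigma2 <- rss / df
    XtXinv <- chol2inv(qr.R(qrd))
    se <- sqrt(sigma2 * XtXinv[1, 1])
    tstat <- coefs[1, ] / se
    # an exactly reproduced gene with zero contrast effect is 0/0: no
    # evidence against the null
    scale <- sqrt(rowMeans(pseudoMeans^2)) + 1e-300
    degen <- se < 1e-10 * scale & abs(coefs[1, ]) < 1e-10 * scale
    tstat[degen] <- 0
    pval <- 2 * pt(-abs(tstat), df = df)
    DataFrame(lfc = unname(coefs[1, ] / log(2)), pval = unname(pval),
              row.names = rownames(pseudoMeans))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the FDR; NA entries are excluded
#' from the adjustment and stay NA.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted p-values of the same length.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- p.adjust(p[ok], method = "BH")
    out
}
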