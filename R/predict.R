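# Counterfactual prediction and the per-cell differential expression matrix.

#' Predict expression at an arbitrary design row
#'
#' \eqn{\hat Y_{:c} = R(x) S(x) Z'_{:c} + \gamma(x) + R(x) s_0(x)} for any
#' latent coordinates \eqn{Z'} — the stored cells (default), or synthetic
#' positions such as the output of [interpolateLatent()]. Predicting a cell
#' at its own observed condition returns its model reconstruction (the
#' denoised observation).
#'
#' @param fit a [LemurFit-class].
#' @param designRow numeric length-K design row at which to predict. A
#'   warning is raised when it lies outside the span of the observed rows
#'   (extrapolation).
#' @param Zprime optional P x n matrix of aligned latent coordinates;
#'   defaults to the full stored embedding.
#' @return G x n matrix of predicted variance-stabilized expression.
#' @export
predictExpression <- function(fit, designRow, Zprime = NULL) {
    stopifnot(is(fit, "LemurFit"))
    if (is.null(Zprime)) Zprime <- fit@embedding
    designRow <- as.numeric(designRow)
    if (length(designRow) != ncol(fit@design))
        stop("designRow must have length K = ", ncol(fit@design))
    .warnIfExtrapolating(fit, designRow)
    R <- .subspaceAt(fit@basePoint, fit@coefB, designRow)
    al <- .alignAt(fit@alignW, fit@alignW0, designRow)
    out <- R %*% (al$S %*% Zprime + al$s0) + .gammaAt(fit@gamma, designRow)
    dimnames(out) <- list(rownames(fit), colnames(Zprime))
    out
}

.warnIfExtrapolating <- function(fit, designRow) {
    Xd <- .uniqueRows(fit@design)$Xd
    qrd <- qr(t(Xd))
    resid <- designRow - t(Xd) %*% qr.coef(qrd, designRow)
    resid[is.na(resid)] <- 0
    if (sqrt(sum(resid^2)) > 1e-8 * max(1, sqrt(sum(designRow^2))))
        warning("design row lies outside the span of the observed ",
                "conditions; the prediction extrapolates")
}

#' Build a design row from covariate values
#'
#' Evaluates the stored design specification (formula) on a one-row
#' data.frame of covariate values, e.g. \code{designRowFor(fit,
#' data.frame(condition = "treated"))}. Spline bases stored in the formula
#' are evaluated at the supplied covariate value with the knots determined at
#' fit time.
#'
#' @param fit a [LemurFit-class] fitted with a formula design.
#' @param newdata one-row data.frame naming the covariates.
#' @return numeric length-K design row.
#' @export
designRowFor <- function(fit, newdata) {
    if (is.null(fit@designSpec))
        stop("the fit was built from an explicit design matrix; ",
             "supply numeric design rows directly")
    mf <- model.frame(fit@designSpec, data = as.data.frame(colData(fit)))
    tt <- terms(mf)
    newmm <- model.matrix(tt, data = model.frame(tt, newdata,
                                                 xlev = .factorLevels(mf)))
    drop(newmm[1, ])
}

.factorLevels <- function(mf) {
    fac <- vapply(mf, is.factor, logical(1))
    lapply(mf[fac], levels)
}

#' Predicted differential expression for a contrast
#'
#' For every cell (training and held-out), the difference between its
#' predicted expression under the two conditions of a contrast:
#' \eqn{\Delta_{:c} = \hat Y^B_{:c} - \hat Y^A_{:c}}, evaluated at the cell's
#' own latent coordinates. \eqn{\Delta} is reported on the
#' variance-stabilized scale (predicted log fold change); it is exactly zero
#' when the rows coincide and antisymmetric under swapping them.
#'
#' @param fit a [LemurFit-class].
#' @param rowA,rowB numeric length-K design rows (condition A and B), e.g.
#'   from [designRowFor()].
#' @param label contrast label for reporting.
#' @return G x C matrix of predicted differences.
#' @export
computeDelta <- function(fit, rowA, rowB, label = "B vs A") {
    rowA <- as.numeric(rowA); rowB <- as.numeric(rowB)
    K <- ncol(fit@design)
    stopifnot(length(rowA) == K, length(rowB) == K)
    .warnIfExtrapolating(fit, rowA)
    .warnIfExtrapolating(fit, rowB)
    Ra <- .subspaceAt(fit@basePoint, fit@coefB, rowA)
    Rb <- .subspaceAt(fit@basePoint, fit@coefB, rowB)
    ala <- .alignAt(fit@alignW, fit@alignW0, rowA)
    alb <- .alignAt(fit@alignW, fit@alignW0, rowB)
    Mdiff <- Rb %*% alb$S - Ra %*% ala$S
    vdiff <- drop(Rb %*% alb$s0 - Ra %*% ala$s0 +
                  .gammaAt(fit@gamma, rowB) - .gammaAt(fit@gamma, rowA))
    out <- Mdiff %*% fit@embedding + vdiff
    dimnames(out) <- dimnames(fit)
    out
}

#' Linear interpolation between two latent positions
#'
#' Evenly spaced convex combinations of two latent coordinates, including
#' both endpoints — synthetic cells at which expression can be predicted in
#' any condition.
#'
#' @param zStart,zEnd numeric length-P coordinates.
#' @param nPoints number of points (>= 2).
#' @return P x nPoints matrix.
#' @export
interpolateLatent <- function(zStart, zEnd, nPoints) {
    stopifnot(length(zStart) == length(zEnd))
    if (nPoints < 2) stop("nPoints must be at least 2")
    tt <- seq(0, 1, length.out = nPoints)
    outer(as.numeric(zStart), 1 - tt) + outer(as.numeric(zEnd), tt)
}
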