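#' @import methods
#' @importFrom stats sd rnorm rnbinom runif kmeans model.matrix pchisq pt
#'   p.adjust optimize terms model.frame dnbinom dpois setNames var quantile
#'   glm.fit poisson update
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assays assayNames colData rowData
#'   SummarizedExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

#' A point on the Grassmann manifold Gr(G, P)
#'
#' Represents a P-dimensional linear subspace of G-dimensional gene space by
#' one orthonormal G x P representative of its equivalence class. Two points
#' are the same subspace iff all their principal angles vanish; subspace
#' identity is therefore always tested with [principalAngles()], never by
#' comparing basis matrices.
#'
#' @slot basis a numeric G x P matrix with orthonormal columns.
#'
#' @seealso [grassmannExp()], [grassmannLog()], [orthonormalize()]
#' @export
setClass("GrassmannPoint", representation(basis = "matrix"))

setValidity("GrassmannPoint", function(object) {
    b <- object@basis
    if (!is.numeric(b) || anyNA(b))
        return("basis must be a finite numeric matrix")
    G <- nrow(b); P <- ncol(b)
    if (P >= G)
        return("subspace dimension P must be smaller than ambient dimension G")
    gram <- crossprod(b)
    if (sqrt(sum((gram - diag(P))^2)) > 1e-10)
        return("basis columns are not orthonormal (|t(B) B - I|_F > 1e-10)")
    TRUE
})

#' A tangent vector on the Grassmann manifold
#'
#' A direction of subspace change anchored at a base point, stored as a
#' G x P matrix in the horizontal space: \code{t(basis(base)) %*% coords = 0}.
#'
#' @slot coords numeric G x P matrix of tangent coordinates.
#' @slot base the [GrassmannPoint-class] the vector is anchored at.
#'
#' @export
setClass("GrassmannTangent",
         representation(coords = "matrix", base = "GrassmannPoint"))

setValidity("GrassmannTangent", function(object) {
    b <- object@base@basis
    v <- object@coords
    if (!identical(dim(b), dim(v)))
        return("tangent coords must have the same dimensions as the base basis")
    if (anyNA(v) || !all(is.finite(v)))
        return("tangent coords must be finite")
    horiz <- crossprod(b, v)
    if (max(abs(horiz)) > 1e-8)
        return("tangent is not horizontal: t(base) %*% coords != 0")
    TRUE
})

#' Fitted multi-condition latent embedding regression model
#'
#' Extends [SingleCellExperiment-class]. The assays hold the input data
#' (\code{counts} if available, \code{logcounts} with the variance-stabilized
#' values the model was fitted on). The model describes each cell as
#' \deqn{Y_{:c} = R(x_c) S(x_c) Z'_{:c} + \gamma(x_c) + R(x_c) s_0(x_c) + \epsilon,}
#' where \eqn{R(x) = Exp_o(\sum_k x_k B_{::k})} rotates a common base subspace
#' \eqn{o} along tangent directions \eqn{B}, \eqn{\gamma(x) = \Gamma x} is a
#' per-gene linear offset, and \eqn{S(x) = I + \sum_k x_k W_{::k}},
#' \eqn{s_0(x) = W^{(0)} x} is an optional affine alignment of the latent
#' coordinates (identity when \code{W}, \code{W0} are zero).
#'
#' @slot basePoint the base subspace \eqn{o}, a [GrassmannPoint-class].
#' @slot coefB numeric array G x P x K of tangent coefficients.
#' @slot gamma numeric G x K matrix of offset regression coefficients.
#' @slot alignW numeric array P x P x K (alignment linear part).
#' @slot alignW0 numeric P x K matrix (alignment translation part).
#' @slot embedding numeric P x C matrix of (aligned) latent coordinates Z'.
#' @slot design numeric C x K design matrix.
#' @slot designSpec the formula/terms used to build the design (or NULL).
#' @slot latentDim integer, the latent dimension P.
#' @slot lambdaAlign numeric ridge weight used by the last alignment fit.
#' @slot testMask logical length-C vector; TRUE marks held-out (test) cells
#'   excluded from all parameter estimation.
#' @slot seedUsed integer seed that fixed the train/test split.
#'
#' @seealso [fitLemur()], [predictExpression()], [computeDelta()],
#'   [alignWithSets()]
#' @export
setClass("LemurFit",
    contains = "SingleCellExperiment",
    representation(
        basePoint = "GrassmannPoint",
        coefB = "array",
        gamma = "matrix",
        alignW = "array",
        alignW0 = "matrix",
        embedding = "matrix",
        design = "matrix",
        designSpec = "ANY",
        latentDim = "integer",
        lambdaAlign = "numeric",
        testMask = "logical",
        seedUsed = "integer"))

setValidity("LemurFit", function(object) {
    G <- nrow(object); C <- ncol(object)
    P <- object@latentDim; K <- ncol(object@design)
    if (!identical(dim(object@coefB), c(G, P, K)))
        return("coefB must be a G x P x K array")
    if (!identical(dim(object@gamma), c(G, K)))
        return("gamma must be a G x K matrix")
    if (!identical(dim(object@alignW), c(P, P, K)))
        return("alignW must be a P x P x K array")
    if (!identical(dim(object@alignW0), c(P, K)))
        return("alignW0 must be a P x K matrix")
    if (!identical(dim(object@embedding), c(P, C)))
        return("embedding must be a P x C matrix")
    if (nrow(object@design) != C)
        return("design must have one row per cell")
    if (length(object@testMask) != C)
        return("testMask must have one entry per cell")
    o <- object@basePoint@basis
    for (k in seq_len(K)) {
        if (max(abs(crossprod(o, object@coefB[, , k]))) > 1e-6)
            return("coefB slices must be tangent at the base point")
    }
    TRUE
})

#' Result of the neighborhood-based differential expression pipeline
#'
#' @slot table a [S4Vectors::DataFrame] with one row per gene: the pseudobulk
#'   log2 fold change, LRT/t-test p-value, BH-adjusted p-value, neighborhood
#'   size, and the neighborhood parameters (direction index, end, threshold).
#' @slot neighborhoods named list (per gene) with elements \code{direction}
#'   (unit vector in latent space), \code{end} (\code{"high"}/\code{"low"}),
#'   \code{threshold}, and \code{cells} (character vector of member cell ids,
#'   training and test).
#' @slot contrast list with design rows \code{rowA}, \code{rowB} and a label.
#' @slot config the resolved pipeline configuration (list).
#' @slot delta the G x C matrix of predicted per-cell differences (contrast
#'   B minus A) on the variance-stabilized scale.
#'
#' @seealso [runDePipeline()]
#' @export
setClass("LemurDEResult",
    representation(
        table = "DataFrame",
        neighborhoods = "list",
        contrast = "list",
        config = "list",
        delta = "matrix"))

#' @describeIn GrassmannPoint-class Construct a Grassmann point from an
#'   orthonormal basis matrix (validated).
#' @param basis numeric matrix with orthonormal columns.
#' @export
GrassmannPoint <- function(basis) {
    new("GrassmannPoint", basis = as.matrix(basis))
}

#' @describeIn GrassmannTangent-class Construct a tangent vector anchored at
#'   a base point (validated for horizontality).
#' @param coords numeric G x P matrix.
#' @param base a [GrassmannPoint-class].
#' @export
GrassmannTangent <- function(coords, base) {
    new("GrassmannTangent", coords = as.matrix(coords), base = base)
}

setMethod("show", "GrassmannPoint", function(object) {
    cat(sprintf("GrassmannPoint: %d-dimensional subspace of R^%d\n",
                ncol(object@basis), nrow(object@basis)))
})

setMethod("show", "GrassmannTangent", function(object) {
    cat(sprintf("GrassmannTangent at Gr(%d, %d), |A|_F = %.4g\n",
                nrow(object@coords), ncol(object@coords),
                sqrt(sum(object@coords^2))))
})

setMethod("show", "LemurFit", function(object) {
    callNextMethod()
    cat(sprintf("latentDim: %d, design columns: %s\n", object@latentDim,
                paste(colnames(object@design), collapse = ", ")))
    cat(sprintf("training cells: %d, test cells: %d, alignment: %s\n",
                sum(!object@testMask), sum(object@testMask),
                if (all(object@alignW == 0) && all(object@alignW0 == 0))
                    "identity" else "fitted"))
})

setMethod("show", "LemurDEResult", function(object) {
    n <- nrow(object@table)
    nsig <- sum(object@table$adjPval < object@config$nominalFdr, na.rm = TRUE)
    cat(sprintf("LemurDEResult: %d genes tested, %d with adjusted p < %.2g (%s)\n",
                n, nsig, object@config$nominalFdr, object@contrast$label))
})
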