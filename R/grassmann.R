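# Grassmann-manifold primitives.
#
# A subspace is stored as one orthonormal representative; all equality checks
# go through principal angles because representatives are only defined up to
# right-multiplication by an orthogonal matrix.

#' Orthonormalize a matrix into a Grassmann point
#'
#' Computes an orthonormal basis of the column space of \code{m} via QR with a
#' deterministic sign convention: the largest-magnitude entry of each column is
#' made positive (first such entry on ties). The convention removes the sign
#' ambiguity of QR/SVD factors so that repeated fits are bitwise reproducible.
#'
#' @param m numeric G x P matrix of full column rank, P < G.
#' @return a [GrassmannPoint-class] spanning the same column space.
#' @examples
#' orthonormalize(cbind(c(2, 0, 0), c(0, 3, 0)))
#' @export
orthonormalize <- function(m) {
    m <- as.matrix(m)
    qrd <- qr(m)
    if (qrd$rank < ncol(m))
        stop("input matrix is rank deficient (rank ", qrd$rank,
             " < ", ncol(m), " columns)")
    q <- qr.Q(qrd)[, seq_len(ncol(m)), drop = FALSE]
    GrassmannPoint(.fixSigns(q))
}

# Deterministic sign convention for orthonormal columns.
.fixSigns <- function(q) {
    for (j in seq_len(ncol(q))) {
        i <- which.max(abs(q[, j]))
        if (q[i, j] < 0) q[, j] <- -q[, j]
    }
    q
}

#' Exponential map on the Grassmann manifold
#'
#' Moves from a base subspace along a tangent direction. With the thin SVD
#' \eqn{A = U diag(d) V^T} of the tangent coordinates, the target
#' representative is \eqn{o V diag(\cos d) V^T + U diag(\sin d) V^T}. The
#' output is re-orthonormalized to guard against floating-point drift.
#'
#' @param base a [GrassmannPoint-class].
#' @param tangent a [GrassmannTangent-class] anchored at \code{base}.
#' @return a [GrassmannPoint-class].
#' @examples
#' o <- GrassmannPoint(matrix(c(1, 0), ncol = 1))
#' a <- GrassmannTangent(matrix(c(0, pi / 2), ncol = 1), o)
#' grassmannExp(o, a)  # spans (0, 1)
#' @export
grassmannExp <- function(base, tangent) {
    stopifnot(is(base, "GrassmannPoint"), is(tangent, "GrassmannTangent"))
    if (!identical(dim(base@basis), dim(tangent@base@basis)) ||
        max(abs(base@basis - tangent@base@basis)) > 1e-10)
        stop("tangent is not anchored at the supplied base point")
    o <- base@basis
    A <- tangent@coords
    if (max(abs(A)) == 0) return(GrassmannPoint(o))
    sv <- svd(A)
    res <- o %*% sv$v %*% (cos(sv$d) * t(sv$v)) +
        sv$u %*% (sin(sv$d) * t(sv$v))
    # Frame-preserving re-orthonormalization (polar retraction): counter
    # floating-point drift for large |A| without rotating or sign-flipping
    # the frame, which cross-condition predictions rely on. QR would fix
    # signs per column and break that coherence.
    e <- eigen(crossprod(res), symmetric = TRUE)
    invSqrt <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
    GrassmannPoint(res %*% invSqrt)
}

#' Logarithm map on the Grassmann manifold
#'
#' Inverse of [grassmannExp()]: the tangent vector at \code{base} whose
#' exponential spans \code{target}. Computed as
#' \eqn{M = (I - o o^T) q (o^T q)^{-1}}, \eqn{M = U diag(\sigma) V^T},
#' \eqn{A = U diag(\arctan\sigma) V^T}. Defined only when all principal
#' angles between the subspaces are below \eqn{\pi/2}.
#'
#' @param base,target [GrassmannPoint-class] objects of identical dimensions.
#' @return a [GrassmannTangent-class] anchored at \code{base}.
#' @export
grassmannLog <- function(base, target) {
    stopifnot(is(base, "GrassmannPoint"), is(target, "GrassmannPoint"))
    o <- base@basis
    q <- target@basis
    if (!identical(dim(o), dim(q)))
        stop("base and target must live on the same Grassmann manifold")
    otq <- crossprod(o, q)
    if (rcond(otq) < 1e-12)
        stop("antipodal subspace: a principal angle reaches pi/2, ",
             "the logarithm map is undefined")
    M <- (q - o %*% otq) %*% solve(otq)
    sv <- svd(M)
    A <- sv$u %*% (atan(sv$d) * t(sv$v))
    # project out numerical leakage along the base before validation
    A <- A - o %*% crossprod(o, A)
    GrassmannTangent(A, base)
}

#' Principal angles between two subspaces
#'
#' The arccosines of the singular values of \eqn{p^T q} (clipped into
#' \eqn{[0, 1]}), sorted ascending. Because \eqn{\arccos} loses about half
#' the machine digits near 1, angles below \eqn{\pi/4} are recomputed from
#' the sine-based factor \eqn{(I - p p^T) q} (Knyazev-Argentati hybrid),
#' which resolves angles down to machine precision. All P angles are zero
#' iff the subspaces coincide; \eqn{\pi/2} marks an orthogonal direction.
#'
#' @param p,q [GrassmannPoint-class] objects of identical dimensions.
#' @return numeric vector of P angles in \eqn{[0, \pi/2]}, ascending.
#' @export
principalAngles <- function(p, q) {
    stopifnot(is(p, "GrassmannPoint"), is(q, "GrassmannPoint"))
    if (!identical(dim(p@basis), dim(q@basis)))
        stop("subspaces must have identical ambient and subspace dimensions")
    ptq <- crossprod(p@basis, q@basis)
    angCos <- sort(acos(pmin(pmax(svd(ptq, nu = 0, nv = 0)$d, 0), 1)))
    sSin <- svd(q@basis - p@basis %*% ptq, nu = 0, nv = 0)$d
    angSin <- rev(asin(pmin(pmax(sSin, 0), 1)))
    small <- angCos < pi / 4
    angCos[small] <- angSin[small]
    angCos
}

#' @describeIn GrassmannTangent-class The zero tangent vector at a base point.
#' @export
zeroTangent <- function(base) {
    GrassmannTangent(matrix(0, nrow(base@basis), ncol(base@basis)), base)
}
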