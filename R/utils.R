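# Internal helpers shared across modules.

# Unique design rows ("conditions") and the cell -> condition grouping.
# Returns Xd (J x K matrix of distinct rows), group (length-C integer index
# into the rows of Xd) and counts (cells per condition).
.uniqueRows <- function(X) {
    key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
    uk <- unique(key)
    group <- match(key, uk)
    first <- match(uk, key)
    Xd <- X[first, , drop = FALSE]
    rownames(Xd) <- NULL
    list(Xd = Xd, group = group, counts = tabulate(group, length(uk)))
}

# gamma(x) for a single design row
.gammaAt <- function(gamma, x) drop(gamma %*% x)

# R(x) = Exp_o(sum_k x_k B_::k) for a single design row
.subspaceAt <- function(basePoint, coefB, x) {
    P <- dim(coefB)[2]
    A <- matrix(0, nrow(basePoint@basis), P)
    for (k in seq_along(x))
        if (x[k] != 0) A <- A + x[k] * coefB[, , k]
    # numerical re-projection onto the horizontal space
    A <- A - basePoint@basis %*% crossprod(basePoint@basis, A)
    grassmannExp(basePoint, GrassmannTangent(A, basePoint))@basis
}

# S(x) = I + sum_k x_k W_::k and s0(x) = W0 x
.alignAt <- function(alignW, alignW0, x) {
    P <- dim(alignW)[1]
    S <- diag(P)
    for (k in seq_along(x))
        if (x[k] != 0) S <- S + x[k] * alignW[, , k]
    list(S = S, s0 = drop(alignW0 %*% x))
}

# Minimum-norm (ridge-free) weighted least squares: minimise
# sum_j w_j |Y[, j] - X[j, ] beta|^2 over each response row of Y.
# Y is R x J (responses in rows), X is J x K. Returns R x K coefficients,
# using the pseudoinverse when X has fewer rows than columns.
.weightedLsMinNorm <- function(Y, X, w) {
    sw <- sqrt(w)
    Xw <- X * sw
    Yw <- t(t(Y) * sw)   # scale columns j by sw_j
    sv <- svd(Xw)
    pos <- sv$d > max(sv$d[1], 1) * 1e-12
    # beta^T = V diag(1/d) U^T Yw^T
    t(sv$v[, pos, drop = FALSE] %*%
          ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], t(Yw))))
}

# Extract the variance-stabilized values matrix from a fit or SE-like object.
.valuesMatrix <- function(object) {
    if (is(object, "SummarizedExperiment")) {
        if ("logcounts" %in% assayNames(object))
            return(as.matrix(assay(object, "logcounts")))
        stop("no 'logcounts' assay present")
    }
    as.matrix(object)
}

# Row cumulative sums of a dense matrix (genes x ordered cells).
.rowCumsum <- function(m) {
    if (nrow(m) == 1L) return(matrix(cumsum(m[1, ]), nrow = 1))
    t(apply(m, 1L, cumsum))
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
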