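# Optional affine alignment of latent coordinates across conditions, driven
# by user-supplied matching sets (landmark annotations or any external
# clustering whose groups span several conditions).
#
# The alignment objective is nonlinear in (W, W0) because the inverse map
# S^{-1} acts on the coordinates. We therefore fit the inverse map directly:
# for every distinct design row, a ridge-penalized affine map
# H(z) = H1 z + h0 minimizing sum |M_e - H(z_c)|^2 + lambda |H - identity|^2,
# which is linear least squares, and then convert S(x) = H1^{-1},
# s0(x) = -H1^{-1} h0 back to the W/W0 parameterization by solving the linear
# system S(x_j) = I + sum_k x_jk W_::k across the distinct design rows.

# Normalize a matching-set specification to a list of integer cell indices.
.normalizeSets <- function(sets, cellIds, C) {
    if (!is.list(sets)) {
        # grouping vector, NA = unmatched
        stopifnot(length(sets) == C)
        sets <- split(seq_len(C), sets)
    } else {
        sets <- lapply(sets, function(s) {
            if (is.character(s)) match(s, cellIds) else as.integer(s)
        })
    }
    for (s in sets)
        if (anyNA(s) || any(s < 1L) || any(s > C))
            stop("matching sets contain unknown cell identifiers")
    if (anyDuplicated(unlist(sets)))
        stop("matching sets must be pairwise disjoint")
    sets
}

# Unaligned projection coordinates Z = S(x) Z' + s0(x).
.rawEmbedding <- function(fit) {
    Z <- fit@embedding
    if (all(fit@alignW == 0) && all(fit@alignW0 == 0)) return(Z)
    rows <- .uniqueRows(fit@design)
    out <- Z
    for (j in seq_len(nrow(rows$Xd))) {
        idx <- which(rows$group == j)
        al <- .alignAt(fit@alignW, fit@alignW0, rows$Xd[j, ])
        out[, idx] <- al$S %*% Z[, idx, drop = FALSE] + al$s0
    }
    out
}

#' Fit the affine alignment from matching sets
#'
#' Estimates \eqn{S(x) = I + \sum_k x_k W_{::k}} and \eqn{s_0(x) = W^{(0)} x}
#' so that, for every matching set, the aligned coordinates of its member
#' cells move toward the set's mean latent coordinate, with a ridge penalty
#' \eqn{\lambda (|W|^2 + |W^{(0)}|^2)} pulling the alignment toward the
#' identity. With no matching sets the alignment is exactly the identity.
#' Sets whose members span fewer than two distinct conditions carry no
#' alignment information and are dropped with a warning.
#'
#' Re-parameterizing the embedding never changes self-condition
#' reconstructions: \eqn{R(x)(S(x) Z' + s_0(x)) + \gamma(x) = R(x) Z +
#' \gamma(x)} by construction.
#'
#' @param fit a [LemurFit-class].
#' @param sets matching sets: a list of cell indices / cell-id vectors, or a
#'   length-C grouping vector with NA for unmatched cells.
#' @param lambda positive ridge weight; default \code{0.01 *} the number of
#'   matched cells.
#' @param verbose emit progress messages.
#' @return the fit with \code{alignW}, \code{alignW0} filled and the
#'   embedding updated to the aligned coordinates.
#' @export
alignWithSets <- function(fit, sets, lambda = NULL, verbose = FALSE) {
    stopifnot(is(fit, "LemurFit"))
    C <- ncol(fit); P <- fit@latentDim; K <- ncol(fit@design)
    sets <- .normalizeSets(sets, colnames(fit), C)
    if (length(sets) == 0) return(.setAlignment(fit,
        array(0, c(P, P, K)), matrix(0, P, K), NA_real_))

    rowsAll <- .uniqueRows(fit@design)
    spanning <- vapply(sets, function(s)
        length(unique(rowsAll$group[s])) >= 2L, logical(1))
    if (any(!spanning))
        warning(sum(!spanning), " matching set(s) spanned a single condition",
                " and were dropped")
    sets <- sets[spanning]
    if (length(sets) == 0) {
        warning("no usable matching sets; alignment left at the identity")
        return(.setAlignment(fit, array(0, c(P, P, K)), matrix(0, P, K),
                             NA_real_))
    }

    Zraw <- .rawEmbedding(fit)
    member <- unlist(sets)
    setOf <- rep(seq_along(sets), lengths(sets))
    Msets <- vapply(sets, function(s)
        rowMeans(Zraw[, s, drop = FALSE]), numeric(P))  # P x E
    if (is.null(lambda)) lambda <- 0.01 * length(member)
    stopifnot(lambda > 0)

    # per-condition inverse affine maps
    grpM <- rowsAll$group[member]
    condsM <- sort(unique(grpM))
    Hlist <- list()
    for (j in condsM) {
        cj <- member[grpM == j]
        z <- Zraw[, cj, drop = FALSE]
        M <- Msets[, setOf[grpM == j], drop = FALSE]
        Zc <- rbind(z, 1)
        Tmat <- cbind(diag(P), rep(0, P))
        H <- (tcrossprod(M, Zc) + lambda * Tmat) %*%
            solve(tcrossprod(Zc) + lambda * diag(P + 1))
        H1 <- H[, seq_len(P), drop = FALSE]
        if (rcond(H1) < 1e-12)
            stop("singular per-condition affine map for condition ", j)
        Hlist[[as.character(j)]] <-
            list(S = solve(H1), s0 = -solve(H1, H[, P + 1]), n = length(cj))
    }

    # recover W, W0 from the per-condition maps across distinct design rows
    Xd <- rowsAll$Xd[condsM, , drop = FALSE]
    w <- vapply(Hlist, `[[`, numeric(1), "n")
    Starget <- vapply(Hlist, function(h) as.vector(h$S - diag(P)),
                      numeric(P * P))      # (P*P) x Jm
    s0target <- vapply(Hlist, `[[`, numeric(P), "s0")
    if (P == 1) s0target <- matrix(s0target, nrow = 1)
    Wflat <- .weightedLsMinNorm(matrix(Starget, nrow = P * P), Xd, w)
    W <- array(Wflat, dim = c(P, P, K))
    W0 <- matrix(.weightedLsMinNorm(s0target, Xd, w), P, K)

    # every observed condition must stay invertible
    for (j in seq_len(nrow(rowsAll$Xd))) {
        S <- .alignAt(W, W0, rowsAll$Xd[j, ])$S
        if (rcond(S) < 1e-10)
            stop("fitted alignment is numerically singular for condition ", j)
    }

    # accept only if the alignment objective improves over the identity
    objAt <- function(Wa, W0a) {
        tot <- lambda * (sum(Wa^2) + sum(W0a^2))
        for (j in condsM) {
            cj <- member[grpM == j]
            al <- .alignAt(Wa, W0a, rowsAll$Xd[j, ])
            zp <- solve(al$S, Zraw[, cj, drop = FALSE] - al$s0)
            tot <- tot + sum((Msets[, setOf[grpM == j], drop = FALSE] - zp)^2)
        }
        tot
    }
    if (objAt(W, W0) > objAt(array(0, c(P, P, K)), matrix(0, P, K))) {
        .msg(verbose, "alignment did not improve the objective; ",
             "keeping the identity")
        W <- array(0, c(P, P, K)); W0 <- matrix(0, P, K)
    }
    .setAlignment(fit, W, W0, lambda)
}

.setAlignment <- function(fit, W, W0, lambda) {
    Zraw <- .rawEmbedding(fit)
    fit@alignW <- W
    fit@alignW0 <- W0
    fit@lambdaAlign <- lambda
    fit@embedding <- applyAlignment(fit, Zraw, fit@design)
    fit
}

#' Apply (or invert) the fitted alignment
#'
#' Forward: \eqn{Z' = S^{-1}(x) (Z - s_0(x))} maps raw projection coordinates
#' to aligned coordinates. With \code{inverse = TRUE}, maps aligned
#' coordinates back: \eqn{Z = S(x) Z' + s_0(x)}. With zero alignment
#' parameters both directions are the identity.
#'
#' @param fit a [LemurFit-class].
#' @param Z numeric P x n coordinate matrix.
#' @param X numeric n x K design matrix (or single length-K row).
#' @param inverse apply the forward model map instead of its inverse.
#' @return P x n matrix.
#' @export
applyAlignment <- function(fit, Z, X, inverse = FALSE) {
    if (is.null(dim(X))) X <- matrix(X, nrow = ncol(Z), ncol = length(X),
                                     byrow = TRUE)
    stopifnot(nrow(Z) == fit@latentDim, nrow(X) == ncol(Z))
    rows <- .uniqueRows(X)
    out <- Z
    for (j in seq_len(nrow(rows$Xd))) {
        idx <- which(rows$group == j)
        al <- .alignAt(fit@alignW, fit@alignW0, rows$Xd[j, ])
        if (rcond(al$S) < 1e-10)
            stop("alignment map is numerically singular for a supplied row")
        out[, idx] <- if (inverse)
            al$S %*% Z[, idx, drop = FALSE] + al$s0
        else
            solve(al$S, Z[, idx, drop = FALSE] - al$s0)
    }
    out
}
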