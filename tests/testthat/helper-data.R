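# Shared fixture builders. Everything is generated in code at test time.

# Random orthonormal basis / Grassmann point.
randomPoint <- function(G, P) {
    orthonormalize(matrix(rnorm(G * P), G, P))
}

# Random horizontal tangent at `base` with Frobenius norm `len`.
randomTangent <- function(base, len) {
    b <- basis(base)
    m <- matrix(rnorm(nrow(b) * ncol(b)), nrow(b), ncol(b))
    m <- m - b %*% crossprod(b, m)
    GrassmannTangent(m / sqrt(sum(m^2)) * len, base)
}

# Noiseless two-condition data generated from a known model whose base point
# is the balanced center of the two condition subspaces (symmetric +/- A
# tangents) and whose shared latent coordinates are exactly isotropic and
# centered. Under this construction the pooled-PCA base point estimator and
# the per-condition tangents are exact, so parameter recovery and
# cross-condition prediction can be checked at numerical precision.
makeRecoveryData <- function(G = 30, P = 3, nPerCond = 80,
                             tangentNorm = pi / 5, seed = 11) {
    set.seed(seed)
    o <- randomPoint(G, P)
    A <- randomTangent(o, tangentNorm)
    RA <- basis(grassmannExp(o, GrassmannTangent(-A@coords, o)))
    RB <- basis(grassmannExp(o, A))
    Z0 <- matrix(rnorm(P * nPerCond), P, nPerCond)
    Z0 <- Z0 - rowMeans(Z0)
    Z <- t(qr.Q(qr(t(Z0)))) * sqrt(nPerCond)     # Z Z^T = n I exactly
    gamA <- rnorm(G); gamB <- rnorm(G)
    Y <- cbind(RA %*% Z + gamA, RB %*% Z + gamB)
    colnames(Y) <- paste0("c", seq_len(ncol(Y)))
    cond <- rep(c("A", "B"), each = nPerCond)
    list(Y = Y, X = stats::model.matrix(~cond), o = o, RA = RA, RB = RB,
         Z = Z, gamA = gamA, gamB = gamB, nPerCond = nPerCond)
}

# Two-condition latent data where condition B's cloud is a known invertible
# affine image of matched groups in condition A; used to test alignment.
makeAffineMisalignment <- function(G = 12, P = 2, nGrp = 5, per = 50,
                                   scatter = 0.002, seed = 5) {
    set.seed(seed)
    o <- randomPoint(G, P)
    gamma <- rnorm(G)
    centers <- matrix(rnorm(P * nGrp, sd = 2), P, nGrp)
    Astar <- matrix(c(1.2, -0.2, 0.3, 0.9), 2, 2)
    bstar <- c(1, -0.5)
    grp <- rep(seq_len(nGrp), each = per)
    ZA <- centers[, grp] + matrix(rnorm(P * length(grp), sd = scatter), P)
    ZBid <- centers[, grp] + matrix(rnorm(P * length(grp), sd = scatter), P)
    ZBobs <- Astar %*% ZBid + bstar
    Y <- cbind(basis(o) %*% ZA + gamma, basis(o) %*% ZBobs + gamma)
    colnames(Y) <- paste0("c", seq_len(ncol(Y)))
    cond <- rep(c("A", "B"), each = length(grp))
    list(Y = Y, X = stats::model.matrix(~cond), o = o, gamma = gamma,
         Astar = Astar, bstar = bstar, groups = c(grp, grp), cond = cond,
         ZBid = ZBid, sets = split(seq_len(ncol(Y)), c(grp, grp)))
}

# Tiny deterministic count SCE with sample/condition structure.
makeTinyCountData <- function(nGenes = 60, nCellsPerSample = 40,
                              nSamplesPerCond = 2, seed = 42) {
    sim <- simulateBenchmarkCounts(
        nGenesNull = nGenes, nGenesDe = 0,
        samplesPerCondition = nSamplesPerCond,
        cellsPerSample = nCellsPerSample, seed = seed)
    sim
}

# Reconstruction of every stored cell at its own condition.
reconstructAll <- function(fit) {
    Z <- latentEmbedding(fit)
    X <- designMatrix(fit)
    out <- matrix(NA_real_, nrow(fit), ncol(fit))
    for (j in seq_len(ncol(fit)))
        out[, j] <- predictExpression(fit, X[j, ], Z[, j, drop = FALSE])[, 1]
    out
}
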