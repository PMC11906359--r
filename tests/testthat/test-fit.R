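# The multi-condition PCA fit: PCA reduction, exact parameter recovery on
# model-generated data, embedding properties, and variance accounting.

test_that("intercept-only fits reduce exactly to PCA (subspace, error, variance explained)", {
    set.seed(21)
    Y <- matrix(rnorm(200 * 500), 200, 500) +
        tcrossprod(rnorm(200), rnorm(500)) * 3
    P <- 5
    fit <- fitLemur(Y, ~1, nEmbedding = P, testFraction = 0, seed = 1)
    Yc <- Y - rowMeans(Y)
    sv <- svd(Yc)
    # subspace matches the truncated-SVD oracle
    expect_lt(max(principalAngles(basePoint(fit),
                                  GrassmannPoint(sv$u[, 1:P]))), 1e-6)
    # reconstruction error matches the Eckart-Young optimum
    recon <- reconstructAll(fit)
    errFit <- sum((Y - recon)^2)
    errPca <- sum(sv$d[-(1:P)]^2)
    expect_lt(abs(errFit - errPca) / errPca, 1e-6)
    expect_equal(varianceExplained(fit), 1 - errPca / sum(Yc^2),
                 tolerance = 1e-6)
})

test_that("noiseless model-generated two-condition data is recovered exactly", {
    dat <- makeRecoveryData(G = 30, P = 3, nPerCond = 80,
                            tangentNorm = pi / 5, seed = 11)
    fit <- fitLemur(dat$Y, dat$X, nEmbedding = 3, testFraction = 0, seed = 1)
    Ra <- predictExpression(fit, c(1, 0), diag(3))
    # per-condition subspaces match the generating ones
    RfA <- lemda:::.subspaceAt(basePoint(fit), tangentCoefficients(fit),
                               c(1, 0))
    RfB <- lemda:::.subspaceAt(basePoint(fit), tangentCoefficients(fit),
                               c(1, 1))
    expect_lt(max(principalAngles(GrassmannPoint(RfA),
                                  GrassmannPoint(dat$RA))), 1e-6)
    expect_lt(max(principalAngles(GrassmannPoint(RfB),
                                  GrassmannPoint(dat$RB))), 1e-6)
    # the base point is recovered too (balanced-center construction)
    expect_lt(max(principalAngles(basePoint(fit), dat$o)), 1e-6)
    # counterfactual: predict condition B for the condition-A cells
    n <- dat$nPerCond
    predB <- predictExpression(fit, c(1, 1),
                               latentEmbedding(fit)[, seq_len(n)])
    expect_lt(max(abs(predB - (dat$RB %*% dat$Z + dat$gamB))), 1e-6)
})

test_that("identical data in both conditions gives a vanishing condition tangent", {
    set.seed(13)
    G <- 25; P <- 2; n <- 60
    o <- randomPoint(G, P)
    Z <- matrix(rnorm(P * n), P, n)
    Yhalf <- basis(o) %*% Z + rnorm(G)
    Y <- cbind(Yhalf, Yhalf)
    cond <- rep(c("A", "B"), each = n)
    fit <- fitLemur(Y, stats::model.matrix(~cond), nEmbedding = P,
                    testFraction = 0, seed = 1)
    B <- tangentCoefficients(fit)
    expect_lt(max(abs(B[, , 2])), 1e-8)
})

test_that("embedding is idempotent, residuals orthogonal to the subspace, and gamma-cells map to zero", {
    dat <- makeRecoveryData(seed = 17)
    fit <- fitLemur(dat$Y, dat$X, nEmbedding = 3, testFraction = 0.3,
                    seed = 2)
    Y <- SummarizedExperiment::assay(fit, "logcounts")
    Z2 <- embedCells(fit, Y, designMatrix(fit))
    expect_equal(Z2, latentEmbedding(fit), tolerance = 1e-8)
    # residual of a held-out cell is orthogonal to its condition subspace
    x <- c(1, 1)
    R <- lemda:::.subspaceAt(basePoint(fit), tangentCoefficients(fit), x)
    ynew <- matrix(rnorm(nrow(fit)), ncol = 1)
    z <- embedCells(fit, ynew, matrix(x, 1))
    gam <- offsetCoefficients(fit) %*% x
    resid <- ynew - gam - R %*% z
    expect_lt(max(abs(crossprod(R, resid))), 1e-8)
    # a cell equal to gamma(x) embeds at the origin (no alignment)
    zg <- embedCells(fit, matrix(gam, ncol = 1), matrix(x, 1))
    expect_lt(max(abs(zg)), 1e-8)
    # a cell inside its condition's subspace is reconstructed exactly
    yin <- R %*% rnorm(3) + gam
    zin <- embedCells(fit, matrix(yin, ncol = 1), matrix(x, 1))
    expect_equal(drop(R %*% zin + gam), drop(yin), tolerance = 1e-8)
})

test_that("reconstruction error is non-increasing in the latent dimension", {
    set.seed(30)
    sim <- makeTinyCountData(nGenes = 80, nCellsPerSample = 50, seed = 12)
    Y <- shiftedLogTransform(SummarizedExperiment::assay(sim$dataset,
                                                         "counts"))
    errs <- vapply(c(2, 5, 10), function(P) {
        fit <- fitLemur(Y, sim$design, nEmbedding = P, testFraction = 0,
                        seed = 1)
        sum((Y - reconstructAll(fit))^2)
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
})

test_that("subspaces stay orthonormal for every observed design row", {
    set.seed(31)
    sim <- makeTinyCountData(nGenes = 50, nCellsPerSample = 30, seed = 7)
    fit <- fitLemur(sim$dataset, ~condition, nEmbedding = 4,
                    testFraction = 0.4, seed = 3)
    for (x in split(designMatrix(fit), row(designMatrix(fit)))[c(1, 60)]) {
        R <- lemda:::.subspaceAt(basePoint(fit), tangentCoefficients(fit),
                                 as.numeric(x))
        expect_lt(max(abs(crossprod(R) - diag(4))), 1e-8)
    }
})

test_that("variance explained is 1 for perfect reconstruction and 0 for the null model", {
    dat <- makeRecoveryData(seed = 23)
    fit <- fitLemur(dat$Y, dat$X, nEmbedding = 3, testFraction = 0, seed = 1)
    expect_equal(varianceExplained(fit), 1, tolerance = 1e-8)
    expect_error(varianceExplained(fit, Y = matrix(1, nrow(fit), 4),
                                   X = cbind(1, rep(0:1, 2))), "constant")
})

test_that("train/test split is seeded, reproducible, and excluded from estimation", {
    set.seed(2)
    Y <- matrix(rnorm(40 * 100), 40, 100)
    f1 <- fitLemur(Y, ~1, nEmbedding = 3, testFraction = 0.5, seed = 7)
    f2 <- fitLemur(Y, ~1, nEmbedding = 3, testFraction = 0.5, seed = 7)
    f3 <- fitLemur(Y, ~1, nEmbedding = 3, testFraction = 0.5, seed = 8)
    expect_identical(testMask(f1), testMask(f2))
    expect_false(identical(testMask(f1), testMask(f3)))
    expect_equal(sum(testMask(f1)), 50)
    # parameters depend only on training cells: perturbing test cells
    # leaves the fitted subspace unchanged
    Y2 <- Y
    Y2[, testMask(f1)] <- Y2[, testMask(f1)] + 5
    f4 <- fitLemur(Y2, ~1, nEmbedding = 3, testFraction = 0.5, seed = 7)
    expect_equal(basis(basePoint(f1)), basis(basePoint(f4)),
                 tolerance = 1e-10)
})
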