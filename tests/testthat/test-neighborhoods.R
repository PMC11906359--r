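# Direction sampling, the neighborhood scan (against a brute-force oracle),
# pseudobulk aggregation, the NB-LRT and linear-model tests, and BH.

test_that("sampled directions are unit, seeded, and uniformly spread", {
    d1 <- sampleDirections(30, 100, seed = 1)
    d2 <- sampleDirections(30, 100, seed = 1)
    d3 <- sampleDirections(30, 100, seed = 2)
    expect_equal(sqrt(colSums(d1^2)), rep(1, 100), tolerance = 1e-12)
    expect_identical(d1, d2)
    expect_false(identical(d1, d3))
    # mean pairwise |dot| matches the Monte-Carlo expectation for P = 30
    dots <- abs(crossprod(d1))
    obs <- mean(dots[upper.tri(dots)])
    set.seed(99)
    mc <- replicate(4000, {
        u <- rnorm(30); v <- rnorm(30)
        abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
    })
    expect_lt(abs(obs - mean(mc)), 4 * stats::sd(mc) / sqrt(length(mc)) +
                  0.02)
})

test_that("neighborhood scan matches a brute-force prefix search on a single direction", {
    set.seed(50)
    Ctr <- 120
    z <- matrix(rnorm(Ctr), 1, Ctr)            # P = 1: only +/- e1
    delta <- matrix(rnorm(Ctr, 0.2, 1), 1, Ctr)
    dirs <- matrix(1, 1, 1)
    sel <- selectNeighborhoods(delta, z, dirs, minCells = 10)
    # brute force over every prefix of both orderings
    t <- z[1, ]
    sdd <- stats::sd(delta[1, ])
    best <- -Inf; bestSet <- NULL
    for (endHigh in c(TRUE, FALSE)) {
        ord <- order(t, decreasing = endHigh)
        for (m in 10:Ctr) {
            s <- abs(sum(delta[1, ord[1:m]])) / (sdd * sqrt(m))
            if (s > best) { best <- s; bestSet <- sort(ord[1:m]) }
        }
    }
    expect_equal(sel$stats$score[1], best, tolerance = 1e-12)
    got <- which(neighborhoodMembers(sel$directions[, 1], sel$stats$end[1],
                                     sel$stats$threshold[1], z))
    expect_identical(sort(got), bestSet)
})

test_that("constant positive delta selects all cells; zero delta selects none", {
    set.seed(51)
    z <- matrix(rnorm(2 * 80), 2, 80)
    dirs <- sampleDirections(2, 10, seed = 3)
    deltaConst <- matrix(1, 1, 80) + matrix(rnorm(80, sd = 1e-9), 1, 80)
    sel <- selectNeighborhoods(deltaConst, z, dirs, minCells = 10)
    expect_equal(sel$stats$size[1], 80)
    deltaZero <- matrix(0, 1, 80)
    sel0 <- selectNeighborhoods(deltaZero, z, dirs, minCells = 10)
    expect_true(is.na(sel0$stats$end[1]))
})

test_that("a delta-marked cluster is recovered with high Jaccard overlap across seeds", {
    jac <- vapply(1:10, function(s) {
        set.seed(s)
        n1 <- 60; n2 <- 60
        z <- cbind(matrix(rnorm(2 * n1, mean = 3, sd = 0.5), 2),
                   matrix(rnorm(2 * n2, mean = -3, sd = 0.5), 2))
        delta <- matrix(c(rep(1, n1), rep(0, n2)) +
                            rnorm(n1 + n2, sd = 0.1), 1)
        dirs <- sampleDirections(2, 50, seed = s + 100)
        sel <- selectNeighborhoods(delta, z, dirs, minCells = 10)
        got <- which(neighborhoodMembers(sel$directions[, 1],
                                         sel$stats$end[1],
                                         sel$stats$threshold[1], z))
        length(intersect(got, 1:n1)) / length(union(got, 1:n1))
    }, numeric(1))
    expect_true(all(jac > 0.9))
})

test_that("contrast-procedure scan picks the direction aligned with the delta gradient", {
    set.seed(53)
    n <- 100
    z <- rbind(seq(-3, 3, length.out = n), rnorm(n, sd = 0.2))
    delta <- matrix(ifelse(z[1, ] > 1.5, 1, 0) + rnorm(n, sd = 0.05), 1)
    sel <- selectNeighborhoods(delta, z, procedure = "contrast",
                               minCells = 10)
    v <- sel$directions[, 1]
    expect_gt(abs(v[1]), 0.9)   # dominated by the informative axis
    got <- which(neighborhoodMembers(v, sel$stats$end[1],
                                     sel$stats$threshold[1], z))
    truthSet <- which(z[1, ] > 1.5)
    expect_gt(length(intersect(got, truthSet)) /
                  length(union(got, truthSet)), 0.7)
})

test_that("pseudobulk aggregation sums, averages, and is additive over disjoint sets", {
    vals <- rbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
    sid <- c("s1", "s1", "s2", "s2")
    agg <- pseudobulkAggregate(vals, 1:4, sid, mode = "sum")
    expect_equal(unname(agg$matrix), rbind(c(4, 12), c(6, 14)))
    expect_equal(unname(agg$nCells), c(2L, 2L))
    # one cell per sample returns that cell's values
    one <- pseudobulkAggregate(vals, c(1, 3), sid)
    expect_equal(unname(one$matrix), vals[, c(1, 3)])
    # counts mode: two cells with counts (1,2) and (3,4) in one sample
    two <- pseudobulkAggregate(rbind(c(1, 3), c(2, 4)), 1:2, c("a", "a"))
    expect_equal(unname(two$matrix), cbind(c(4, 6)))
    # additivity over disjoint neighborhoods
    aggA <- pseudobulkAggregate(vals, 1:2, sid, mode = "sum")$matrix
    aggB <- pseudobulkAggregate(vals, 3:4, sid, mode = "sum")$matrix
    aggU <- pseudobulkAggregate(vals, 1:4, sid, mode = "sum")$matrix
    expect_equal(aggA + aggB, aggU)
    # empty samples kept as flagged zero columns, mean mode
    m <- pseudobulkAggregate(vals, 1:2, sid, mode = "mean")
    expect_equal(unname(m$nCells), c(2L, 0L))
    expect_equal(unname(m$matrix[, 2]), c(0, 0))
})

test_that("NB LRT: identical groups give p = 1, null counts give uniform p, moment oracle for the lfc", {
    X <- cbind(1, rep(c(0, 1), each = 3))
    yEq <- matrix(rep(7, 6), 1)
    r <- nbGlmLrt(yEq, X, contrast = c(0, 1))
    expect_equal(unname(r$lfc[1]), 0, tolerance = 1e-6)
    expect_equal(unname(r$pval[1]), 1, tolerance = 1e-6)
    # null calibration: NB counts, no effect, 2000 genes
    set.seed(60)
    G <- 2000
    mu <- exp(rnorm(G, 3, 1))
    y <- matrix(rnbinom(G * 6, mu = rep(mu, 6), size = 1 / 0.2), G, 6)
    rn <- nbGlmLrt(y, X, contrast = c(0, 1))
    ks <- suppressWarnings(stats::ks.test(rn$pval, "punif")$statistic)
    expect_lt(ks, 0.1)
    # moment oracle: group means 10 vs 40 -> log2 fold change 2
    set.seed(61)
    S <- 40
    Xl <- cbind(1, rep(c(0, 1), each = S / 2))
    yl <- matrix(rnbinom(S, mu = rep(c(10, 40), each = S / 2),
                         size = 1000), 1)
    rl <- nbGlmLrt(yl, Xl, contrast = c(0, 1))
    expect_equal(unname(rl$lfc[1]), 2, tolerance = 0.15)
    expect_lt(rl$pval[1], 1e-6)
})

test_that("NB LRT honours offsets", {
    # counts proportional to the offsets carry no signal
    X <- cbind(1, rep(c(0, 1), each = 3))
    off <- log(c(1, 1, 1, 4, 4, 4))
    y <- matrix(c(10, 11, 9, 41, 39, 40), 1)
    r <- nbGlmLrt(y, X, contrast = c(0, 1), offsets = off)
    expect_lt(abs(r$lfc[1]), 0.1)
    expect_gt(r$pval[1], 0.3)
})

test_that("linear-model test reproduces the closed-form two-sample t-test", {
    y <- matrix(c(1, 2, 3, 4, 5, 6), 1)
    X <- cbind(1, rep(c(0, 1), each = 3))
    r <- lmTest(y, X, contrast = c(0, 1))
    oracle <- stats::t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
    expect_equal(unname(r$pval[1]), oracle$p.value, tolerance = 1e-12)
    expect_equal(unname(r$lfc[1]) * log(2), 3, tolerance = 1e-12)
    # identical means give t = 0, p = 1
    r0 <- lmTest(matrix(rep(2, 6), 1), X, contrast = c(0, 1))
    expect_equal(unname(r0$pval[1]), 1, tolerance = 1e-12)
    # adding a constant to all samples changes no p-value
    set.seed(62)
    ym <- matrix(rnorm(30), 5, 6)
    ra <- lmTest(ym, X, contrast = c(0, 1))
    rb <- lmTest(ym + 100, X, contrast = c(0, 1))
    expect_equal(ra$pval, rb$pval, tolerance = 1e-9)
})

test_that("BH adjustment matches the brute-force step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.2), 0.2)
    bruteBH <- function(p) {
        n <- length(p); o <- order(p)
        adj <- p[o] * n / seq_len(n)
        adj <- rev(cummin(rev(adj)))
        out <- numeric(n); out[o] <- pmin(adj, 1); out
    }
    set.seed(63)
    for (i in 1:5) {
        p <- runif(50)
        expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
    }
    pna <- c(0.01, NA, 0.5)
    expect_equal(is.na(bhAdjust(pna)), c(FALSE, TRUE, FALSE))
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("NB LRT agrees with edgeR on strong-signal pseudobulk data", {
    skip_if_not_installed("edgeR")
    set.seed(64)
    S <- 6
    X <- cbind(1, rep(c(0, 1), each = 3))
    mu <- rep(c(20, 80), each = 3)
    y <- matrix(rnbinom(40 * S, mu = rep(mu, each = 40), size = 1 / 0.05),
                40, S)
    ours <- nbGlmLrt(y, X, contrast = c(0, 1))
    dge <- edgeR::DGEList(counts = y, lib.size = rep(1e4, S))
    dge <- edgeR::estimateDisp(dge, design = X)
    fit <- edgeR::glmFit(dge, design = X)
    lrt <- edgeR::glmLRT(fit, coef = 2)
    # independent implementations agree on the effect size
    expect_gt(stats::cor(ours$lfc, lrt$table$logFC), 0.98)
    # and on which genes are clearly significant
    expect_gt(mean((ours$pval < 0.01) == (lrt$table$PValue < 1e-4)), 0.8)
})
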