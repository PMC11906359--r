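# The Gamma-Poisson benchmark simulator, the stylized toy, and the
# evaluation metrics.

test_that("simulated counts match Gamma-Poisson moments", {
    # eta = 0, sf = 1: mean 1; mu = 4, alpha = 0.2: variance 7.2
    sim <- simulateBenchmarkCounts(nGenesNull = 4, nGenesDe = 0,
                                   samplesPerCondition = 1,
                                   cellsPerSample = 200, seed = 1)
    set.seed(70)
    n <- 1e5
    d1 <- rnbinom(n, mu = 1, size = 1 / 0.2)
    expect_lt(abs(mean(d1) - 1), 3 * stats::sd(d1) / sqrt(n))
    d2 <- rnbinom(n, mu = 4, size = 1 / 0.2)
    expect_lt(abs(mean(d2) - 4), 3 * stats::sd(d2) / sqrt(n))
    v2 <- var(d2)
    # variance of the sample variance via fourth moments, rough bound
    expect_lt(abs(v2 - 7.2), 4 * stats::sd((d2 - mean(d2))^2) / sqrt(n))
})

test_that("an implanted log2 fold change of 1 doubles the mean in affected cells", {
    sim <- simulateBenchmarkCounts(nGenesNull = 5, nGenesDe = 40,
                                   cellsPerSample = 400,
                                   lfcLevels = c(1), clusterCounts = c(2L),
                                   sampleEffectSd = 0, sizeFactorSd = 0,
                                   loadingSd = 0, seed = 2)
    counts <- SummarizedExperiment::assay(sim$dataset, "counts")
    cond <- SummarizedExperiment::colData(sim$dataset)$condition
    ratios <- vapply(which(sim$truth$isDe), function(g) {
        aff <- sim$affected[[g]]
        affB <- aff[cond[aff] == "B"]
        offB <- setdiff(which(cond == "B"), aff)
        mean(counts[g, affB]) / mean(counts[g, offB])
    }, numeric(1))
    expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("simulator output is reproducible, correctly structured, and truth-consistent", {
    s1 <- simulateBenchmarkCounts(nGenesNull = 30, nGenesDe = 10,
                                  cellsPerSample = 20, seed = 5)
    s2 <- simulateBenchmarkCounts(nGenesNull = 30, nGenesDe = 10,
                                  cellsPerSample = 20, seed = 5)
    expect_identical(SummarizedExperiment::assay(s1$dataset, "counts"),
                     SummarizedExperiment::assay(s2$dataset, "counts"))
    cd <- SummarizedExperiment::colData(s1$dataset)
    expect_equal(nlevels(cd$sample_id), 6)
    expect_equal(table(as.character(cd$condition)),
                 table(rep(c("A", "B"), each = 60)), ignore_attr = TRUE)
    # affected cells of each DE gene form exactly one k-means cluster
    for (g in which(s1$truth$isDe)) {
        k <- s1$truth$clusterK[g]
        cl <- cd[[paste0("cluster_k", k)]]
        expect_identical(s1$affected[[g]],
                         which(cl == s1$truth$clusterId[g]))
    }
    expect_true(all(s1$truth$lfc[!s1$truth$isDe] == 0))
})

test_that("toy two-gene data reproduces the stylized group-specific delta pattern", {
    toy <- makeToyTwoGene(400, seed = 2)
    toy2 <- makeToyTwoGene(400, seed = 2)
    expect_identical(SummarizedExperiment::assay(toy$dataset, "logcounts"),
                     SummarizedExperiment::assay(toy2$dataset, "logcounts"))
    fit <- fitLemur(toy$dataset, ~condition, nEmbedding = 1,
                    testFraction = 0, seed = 1)
    d <- computeDelta(fit, c(1, 0), c(1, 1))
    grp <- SummarizedExperiment::colData(toy$dataset)$group
    # gene 1 down under treatment only in the left group
    expect_gt(mean(d[1, grp == "left"] < -0.5), 0.95)
    expect_gt(mean(abs(d[1, grp == "right"]) < 0.5), 0.95)
    # gene 2 up under treatment only in the right group
    expect_gt(mean(d[2, grp == "right"] > 0.5), 0.95)
    expect_gt(mean(abs(d[2, grp == "left"]) < 0.5), 0.95)
})

test_that("knn mixing hits its extremes and k/2 for mixed balanced data", {
    set.seed(80)
    # perfectly separated conditions
    emb <- cbind(matrix(rnorm(2 * 50, mean = 10), 2),
                 matrix(rnorm(2 * 50, mean = -10), 2))
    lab <- rep(c("A", "B"), each = 50)
    expect_equal(knnMixing(emb, lab, k = 20), 20)
    # a single condition scores k
    expect_equal(knnMixing(emb, rep("A", 100), k = 20), 20)
    # identically distributed balanced conditions score ~ k/2
    emb2 <- matrix(rnorm(2 * 400), 2)
    lab2 <- rep(c("A", "B"), 200)
    expect_lt(abs(knnMixing(emb2, lab2, k = 20) - 10), 1)
    # invariance under rigid rotation
    th <- 0.7
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(knnMixing(Q %*% emb2, lab2, k = 20),
                 knnMixing(emb2, lab2, k = 20))
})

test_that("adjusted Rand index matches the contingency-table formula", {
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
    # brute-force formula oracle on the printed toy
    ariOracle <- function(a, b) {
        tab <- table(a, b)
        sij <- sum(choose(tab, 2))
        sa <- sum(choose(rowSums(tab), 2))
        sb <- sum(choose(colSums(tab), 2))
        n2 <- choose(length(a), 2)
        exp0 <- sa * sb / n2
        (sij - exp0) / ((sa + sb) / 2 - exp0)
    }
    a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
    expect_equal(adjustedRandIndex(a, b), ariOracle(a, b))
    set.seed(81)
    a2 <- sample(1:4, 200, replace = TRUE)
    b2 <- sample(1:3, 200, replace = TRUE)
    expect_equal(adjustedRandIndex(a2, b2), ariOracle(a2, b2),
                 tolerance = 1e-12)
    # independent labelings at C = 2000 concentrate near 0
    set.seed(82)
    expect_lt(abs(adjustedRandIndex(sample(1:5, 2000, TRUE),
                                    sample(1:5, 2000, TRUE))), 0.05)
    expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
})

test_that("FDP/TPR counting matches direct enumeration", {
    adj <- c(rep(0.01, 10), rep(0.5, 30))
    names(adj) <- paste0("g", 1:40)
    isDe <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 12), rep(FALSE, 18))
    names(isDe) <- names(adj)
    r <- fdpTpr(adj, isDe, nominal = 0.1)
    expect_equal(unname(r["fdp"]), 2 / 10)
    expect_equal(unname(r["tpr"]), 8 / 20)
    # no calls
    r0 <- fdpTpr(setNames(rep(0.9, 5), paste0("g", 1:5)),
                 setNames(rep(TRUE, 5), paste0("g", 1:5)))
    expect_equal(unname(r0), c(0, 0))
    # perfect calls
    r1 <- fdpTpr(setNames(c(0.001, 0.9), c("a", "b")),
                 setNames(c(TRUE, FALSE), c("a", "b")))
    expect_equal(unname(r1), c(0, 1))
})

test_that("cell-group labeling follows the 60%/10% rule with its fallback", {
    groups <- list(a = 1:20, b = 21:40, c = 41:60)
    changed <- c(1:14, 21:22)           # 70% of a, 10% of b, 0% of c
    lab <- labelCellGroups(groups, changed)
    expect_equal(lab, c("positive", "indeterminate", "negative"))
    # 5% changed is negative, 30% indeterminate
    lab2 <- labelCellGroups(list(1:20, 21:40, 41:60),
                            c(1, 21:26, 41:54))
    expect_equal(lab2[1], "negative")
    expect_equal(lab2[2], "indeterminate")
    # a qualifying group needs at least 10 changed cells
    lab3 <- labelCellGroups(list(1:8, 9:100), c(1:6, 9:18))
    expect_false(lab3[1] == "positive" && sum(c(1:6) %in% 1:8) >= 10)
    # fallback: when nothing qualifies, the largest fraction is positive
    lab4 <- labelCellGroups(list(1:20, 21:40), c(1:5, 21))
    expect_equal(lab4[1], "positive")
})

test_that("prediction L2 metrics evaluate their definitions", {
    set.seed(83)
    pred <- matrix(rnorm(50), 10, 5)
    expect_equal(predictionL2Metrics(pred, pred)$meanOverall, 0)
    shifted <- pred + 2
    expect_equal(predictionL2Metrics(shifted, pred)$meanOverall,
                 sqrt(10) * 2, tolerance = 1e-10)
    # identity prediction scores worse than the oracle condition mean
    G <- 20; n <- 200
    effect <- rnorm(G, sd = 2)
    obsA <- matrix(rnorm(G * n), G, n)
    obsB <- matrix(rnorm(G * n), G, n) + effect
    identPred <- obsA
    oraclePred <- obsA + effect
    types <- rep("t1", n)
    mIdent <- predictionL2Metrics(identPred, obsB, types, types)
    mOracle <- predictionL2Metrics(oraclePred, obsB, types, types)
    expect_gt(mIdent$meanOverall, mOracle$meanOverall)
    expect_error(predictionL2Metrics(pred, pred, rep("a", 5), rep("b", 5)),
                 "empty")
})
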