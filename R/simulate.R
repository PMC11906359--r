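# Synthetic data generators: the Gamma-Poisson benchmark simulator with
# implanted cluster-restricted fold changes, and the stylized two-gene toy.

#' Gamma-Poisson benchmark simulator
#'
#' Simulates a multi-sample, multi-condition single-cell count matrix with a
#' latent cell-state backbone and implanted differential expression. Cells
#' live on a Gaussian-mixture backbone in a low-dimensional latent space;
#' k-means partitions of the backbone (one partition per entry of
#' \code{clusterCounts}) provide candidate cell groups. Counts follow
#' \deqn{Y_{gc} \sim GammaPoisson(\mu = 2^{\eta_{gc}} sf_c, \alpha)} with
#' \deqn{\eta_{gc} = \beta^{(0)}_g + w_g^T u_c + \beta^{(DE)}_g
#' x^{(isDE)}_c + \beta^{(samp)}_{g, s(c)},}
#' where \eqn{u_c} is the backbone position (so cell states shape every
#' gene), \eqn{\beta^{(samp)}} are per-sample random effects, and for each
#' implanted gene \eqn{x^{(isDE)}_c} marks the cells of one k-means cluster
#' in the treatment condition. Fold-change levels are paired inversely with
#' cluster granularity: the partition with the fewest (largest) clusters
#' carries the smallest \code{lfcLevels} entry, the finest partition the
#' largest, so smaller affected populations get stronger effects. Samples
#' are split evenly across conditions and cells are assigned to the
#' synthetic conditions through their sample.
#'
#' @param nGenesNull,nGenesDe number of null and implanted genes.
#' @param nConditions number of synthetic conditions (first level is the
#'   control).
#' @param samplesPerCondition,cellsPerSample replicate structure.
#' @param overdispersion Gamma-Poisson overdispersion \eqn{\alpha}
#'   (variance \eqn{\mu + \alpha \mu^2}).
#' @param lfcLevels log2 fold-change levels of implanted genes.
#' @param clusterCounts k-means cluster numbers; paired with
#'   \code{lfcLevels} in order.
#' @param sampleEffectSd sd of the per-sample random effects (log2 scale).
#' @param baselineMean,baselineSd normal parameters of the baseline log2
#'   mean \eqn{\beta^{(0)}}, truncated to [-2, 6].
#' @param backboneDim,backboneComponents latent backbone geometry.
#' @param loadingSd sd of per-gene backbone loadings.
#' @param sizeFactorSd sd of log-normal cell size factors (normalized to
#'   mean 1).
#' @param seed integer seed.
#' @return list with \code{dataset} (a [SingleCellExperiment-class] with
#'   \code{counts}, cell metadata \code{sample_id}, \code{condition}, the
#'   cluster assignments, and the backbone in \code{reducedDims}),
#'   \code{design} (the condition design matrix), \code{truth} (per-gene
#'   DataFrame: \code{isDe}, \code{lfc}, \code{clusterK}, \code{clusterId})
#'   and \code{affected} (per-gene integer vectors of affected cells, NULL
#'   for null genes).
#' @export
simulateBenchmarkCounts <- function(nGenesNull = 2000L, nGenesDe = 200L,
                                    nConditions = 2L,
                                    samplesPerCondition = 3L,
                                    cellsPerSample = 300L,
                                    overdispersion = 0.2,
                                    lfcLevels = c(0.5, 1, 2, 4),
                                    clusterCounts = c(2L, 3L, 10L, 20L),
                                    sampleEffectSd = 0.1,
                                    baselineMean = 1, baselineSd = 1.5,
                                    backboneDim = 10L,
                                    backboneComponents = 5L,
                                    loadingSd = 0.3, sizeFactorSd = 0.25,
                                    seed = 1L) {
    stopifnot(overdispersion > 0, nConditions >= 1, samplesPerCondition >= 1,
              cellsPerSample >= 1, all(lfcLevels > 0),
              length(lfcLevels) == length(clusterCounts))
    set.seed(as.integer(seed))
    S <- nConditions * samplesPerCondition
    C <- S * cellsPerSample
    G <- nGenesNull + nGenesDe
    condLevels <- LETTERS[seq_len(nConditions)]
    sampleCond <- rep(condLevels, each = samplesPerCondition)
    sampleIds <- paste0("s", seq_len(S), "_", sampleCond)
    cellSample <- rep(seq_len(S), each = cellsPerSample)
    cellCond <- factor(sampleCond[cellSample], levels = condLevels)

    compMeans <- matrix(rnorm(backboneComponents * backboneDim, sd = 1.5),
                        backboneComponents, backboneDim)
    comp <- sample.int(backboneComponents, C, replace = TRUE)
    u <- compMeans[comp, , drop = FALSE] +
        matrix(rnorm(C * backboneDim, sd = 0.5), C, backboneDim)

    clusterings <- lapply(clusterCounts, function(k)
        kmeans(u, centers = k, nstart = 5, iter.max = 100)$cluster)
    names(clusterings) <- paste0("k", clusterCounts)

    beta0 <- numeric(G)
    todo <- rep(TRUE, G)
    while (any(todo)) {
        beta0[todo] <- rnorm(sum(todo), baselineMean, baselineSd)
        todo <- beta0 < -2 | beta0 > 6
    }
    loadings <- matrix(rnorm(G * backboneDim, sd = loadingSd), G, backboneDim)
    betaSamp <- matrix(rnorm(G * S, sd = sampleEffectSd), G, S)

    geneIds <- c(sprintf("null_%04d", seq_len(nGenesNull)),
                 sprintf("de_%04d", seq_len(nGenesDe)))
    isDe <- c(rep(FALSE, nGenesNull), rep(TRUE, nGenesDe))
    lfc <- rep(0, G)
    clusterK <- rep(NA_integer_, G)
    clusterId <- rep(NA_integer_, G)
    affected <- vector("list", G)
    names(affected) <- geneIds
    trtCond <- condLevels[nConditions]

    eta <- beta0 + tcrossprod(loadings, u) + betaSamp[, cellSample]
    if (nGenesDe > 0) {
        levelOf <- rep_len(seq_along(lfcLevels), nGenesDe)
        for (i in seq_len(nGenesDe)) {
            g <- nGenesNull + i
            lv <- levelOf[i]
            cl <- clusterings[[lv]]
            pick <- sample.int(clusterCounts[lv], 1)
            members <- which(cl == pick)
            x <- members[cellCond[members] == trtCond]
            eta[g, x] <- eta[g, x] + lfcLevels[lv]
            lfc[g] <- lfcLevels[lv]
            clusterK[g] <- clusterCounts[lv]
            clusterId[g] <- pick
            affected[[g]] <- members
        }
    }

    sf <- exp(rnorm(C, sd = sizeFactorSd))
    sf <- sf / mean(sf)
    mu <- 2^eta * rep(sf, each = G)
    counts <- matrix(rnbinom(G * C, mu = mu, size = 1 / overdispersion), G, C)
    dimnames(counts) <- list(geneIds, sprintf("cell_%05d", seq_len(C)))

    cd <- DataFrame(sample_id = factor(sampleIds[cellSample],
                                       levels = sampleIds),
                    condition = cellCond,
                    row.names = colnames(counts))
    for (nm in names(clusterings)) cd[[paste0("cluster_", nm)]] <-
        clusterings[[nm]]
    sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
    SingleCellExperiment::reducedDim(sce, "backbone") <- u

    truth <- DataFrame(gene = geneIds, isDe = isDe, lfc = lfc,
                       clusterK = clusterK, clusterId = clusterId,
                       row.names = geneIds)
    design <- model.matrix(~condition, data = as.data.frame(cd))
    list(dataset = sce, design = design, truth = truth, affected = affected)
}

#' Stylized two-gene, two-group, two-condition toy dataset
#'
#' Two cell groups ("left"/"right") lie on condition-specific
#' one-dimensional subspaces of a two-gene space. The subspace rotation and
#' offsets are constructed so that gene 1 is less expressed under treatment
#' only in the left group while gene 2 is upregulated only in the right
#' group — the minimal pattern a cluster-free model must resolve and a
#' clustered global test averages away.
#'
#' @param nCells total number of cells (>= 20), split evenly over group x
#'   condition.
#' @param seed integer seed.
#' @param noiseSd observation noise sd around the subspaces.
#' @return list with \code{dataset} (SingleCellExperiment, \code{logcounts}
#'   assay, colData \code{group}, \code{condition}), \code{design}, and
#'   \code{truth}: the constructed per-group expected differences
#'   \code{deltaLeft}, \code{deltaRight} (gene 1 and 2).
#' @export
makeToyTwoGene <- function(nCells = 400L, seed = 1L, noiseSd = 0.05) {
    stopifnot(nCells >= 20)
    set.seed(as.integer(seed))
    theta <- 3 * pi / 4
    deltaRot <- 0.3
    rCtrl <- c(cos(theta), sin(theta))
    rTrt <- c(cos(theta + deltaRot), sin(theta + deltaRot))
    a <- rTrt - rCtrl
    zLeft <- 5; zRight <- -5
    b <- c(-a[1] * zRight,    # gene 1 difference vanishes at the right group
           -a[2] * zLeft)     # gene 2 difference vanishes at the left group
    gammaCtrl <- c(3, 3)
    gammaTrt <- gammaCtrl + b

    nPer <- floor(nCells / 4)
    group <- rep(rep(c("left", "right"), each = nPer), 2)
    condition <- rep(c("ctrl", "trt"), each = 2 * nPer)
    z <- rnorm(length(group), mean = ifelse(group == "left", zLeft, zRight),
               sd = 0.6)
    Y <- vapply(seq_along(z), function(i) {
        r <- if (condition[i] == "ctrl") rCtrl else rTrt
        gm <- if (condition[i] == "ctrl") gammaCtrl else gammaTrt
        r * z[i] + gm + rnorm(2, sd = noiseSd)
    }, numeric(2))
    dimnames(Y) <- list(c("gene1", "gene2"),
                        sprintf("cell_%03d", seq_along(z)))
    cd <- DataFrame(group = group,
                    condition = factor(condition, levels = c("ctrl", "trt")),
                    row.names = colnames(Y))
    sce <- SingleCellExperiment(assays = list(logcounts = Y), colData = cd)
    design <- model.matrix(~condition, data = as.data.frame(cd))
    list(dataset = sce, design = design,
         truth = list(deltaLeft = a * zLeft + b, deltaRight = a * zRight + b))
}
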