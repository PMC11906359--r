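---
title: "Latent embedding multi-condition analysis: model and methods"
author: "lemda maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent embedding multi-condition analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemda)
library(SummarizedExperiment)
```

# The problem

Multi-condition single-cell experiments ask how a treatment, time point, or
other covariate changes gene expression — but the effect is rarely uniform
across cells. Classical workflows first cluster cells into discrete "cell
types" and then test each cluster, which discards within-cluster
heterogeneity and makes results hinge on an arbitrary clustering. `lemda`
instead represents cell state continuously: it fits a latent embedding in
which the low-dimensional subspace approximating the data is a smooth
function of the experimental design, predicts every cell's expression under
every condition, and then finds, per gene, the region of latent space where
the predicted change is consistent, testing it on held-out cells.

# The model

Let $Y$ be a $G \times C$ matrix of variance-stabilized expression values
(genes $\times$ cells) and $X$ a $C \times K$ design matrix, one row per
cell, exactly as in limma/edgeR/DESeq2-style linear modelling. Each cell is
modelled as

$$Y_{:c} = R(x_c)\, S(x_c)\, Z'_{:c} + \gamma(x_c) + R(x_c)\, s_0(x_c) + \varepsilon_{:c},$$

where

* $\gamma(x) = \Gamma x$ is a per-gene linear offset ($\Gamma \in
  \mathbb{R}^{G\times K}$), fitted by ordinary least squares;
* $R(x) = \mathrm{Exp}_{o}\!\left(\sum_k x_k B_{::k}\right)$ is an
  orthonormal $G \times P$ basis that varies with the design row through the
  exponential map on the Grassmann manifold $\mathrm{Gr}(G, P)$, anchored at
  a base subspace $o$ with tangent coefficients $B \in \mathbb{R}^{G\times
  P\times K}$;
* $S(x) = I + \sum_k x_k W_{::k}$, $s_0(x) = W^{(0)} x$ is an optional
  affine alignment of latent coordinates (identity unless matching sets are
  supplied);
* $Z' \in \mathbb{R}^{P\times C}$ are the per-cell latent coordinates.

With a single condition the model collapses to PCA. With several, each
distinct design row ("condition") gets its own subspace, reached from the
common base by rotating along the tangent directions — so the subspaces
change smoothly with the covariates and information is shared across
conditions.

## Fitting

The fit is a deterministic, closed-form two-stage procedure on the training
cells:

1. $\Gamma$ by least squares; residuals $E = Y - \Gamma X^\top$.
2. Base point $o$: top-$P$ left singular subspace of the pooled residuals.
3. Per condition $j$: the top-$P$ subspace of that condition's residuals,
   its Grassmann logarithm $T_j$ at $o$, and $B$ from the cell-count-weighted
   least-squares regression of the $T_j$ on the distinct design rows. For
   one-hot designs this solve is exact.
4. $Z'$: orthogonal projection of each cell's offset residual onto its
   condition's subspace (then alignment-corrected).

A condition with fewer than $2P$ training cells contributes a tangent shrunk
toward the base subspace proportionally to its cell count (zero below $P$
cells), because per-condition PCA is unstable there; a warning reports the
shrinkage. Designs with continuous covariates (e.g. spline bases) are
handled by the same tangent regression over distinct design rows; when most
rows are unique the per-row subspaces carry few cells and the fit shrinks
toward ordinary PCA — a known limitation of the closed-form strategy.

### Identifiability of the base point

Only the per-condition subspaces and the reconstruction are identified by
unpaired data; the base point itself is not, and the cross-condition
correspondence (which latent direction in condition A maps to which in B)
does depend on it. The pooled-PCA choice of $o$ is the balanced center of
the observed conditions and makes intercept-only fits reduce exactly to
PCA. The package's parameter-recovery tests therefore generate ground truth
whose base point *is* the balanced center (symmetric $\pm A$ tangents,
isotropic centered shared coordinates), for which the estimator is exact.

Two numerical conventions matter here. `orthonormalize()` fixes column
signs deterministically so repeated fits are identical. The exponential map
re-orthonormalizes its output with a *polar* retraction rather than QR:
QR's per-column sign fixing would rotate the within-subspace frame
inconsistently across conditions and silently corrupt counterfactual
predictions. Principal angles are computed with the cosine/sine hybrid
(small angles from the sine-based factor), since plain $\arccos$ cannot
resolve angles below $\sqrt{\epsilon} \approx 1.5\times 10^{-8}$.

## Alignment

The alignment objective pulls the latent coordinates of user-supplied
matching sets (landmarks, or any external clustering whose groups span at
least two conditions) toward their common mean, with an $L_2$ penalty
$\lambda(\lVert W\rVert^2 + \lVert W^{(0)}\rVert^2)$ toward the identity.
Because $S^{-1}$ enters the objective nonlinearly, `alignWithSets()` fits
the *inverse* map per condition — a ridge-penalized affine regression of
set means onto member coordinates, which is plain least squares — and
converts back to $(W, W^{(0)})$ by solving the linear system of the
parameterization across distinct design rows (minimum-norm solution when
rows are scarce). At the optimum this surrogate coincides with the original
problem for saturated designs. If the fitted parameters do not improve the
original objective over the identity, the identity is kept. The default
$\lambda$ is $0.01$ per matched cell, a scale-free pull toward identity.
Alignment is a re-parameterization: self-condition reconstructions are
unchanged by construction.

## Prediction and the differential expression matrix

`predictExpression()` evaluates $\hat Y = R(x) S(x) Z' + \gamma(x) + R(x)
s_0(x)$ at any design row for any coordinates — observed cells or synthetic
positions from `interpolateLatent()`. For a contrast $(x_A, x_B)$,
`computeDelta()` returns $\Delta = \hat Y^B - \hat Y^A$ for every cell on
the variance-stabilized scale ("predicted log fold change"). No attempt is
made to attach uncertainty to $\Delta$ itself; inference happens on
pseudobulks of held-out cells.

## Neighborhoods and testing

For each gene, training cells are scanned over 100 random unit directions
in latent space (and both ends of each): every prefix of the projection
ordering with at least 10 cells is scored
$z(N) = \lvert\sum_{c\in N}\delta_c\rvert / (\mathrm{sd}(\delta)\sqrt{\lvert N\rvert})$,
and the best (direction, end, threshold) triple defines the gene's
neighborhood — a half-space of latent space, hence convex, and transferable
to unseen cells by thresholding their own projections. The scan is exactly
brute-force per direction, so a direct enumeration oracle can verify it.
The alternative `selectionProcedure = "contrast"` uses the single per-gene
direction $v_g \propto \sum_c \delta_{gc} z'_c$.

Significance uses pseudobulks of *held-out* cells only (default test
fraction 50%): per gene, member test cells are summed per sample, samples
with no members are dropped, offsets are log normed-sum totals of member
cells, and a negative-binomial GLM likelihood-ratio test compares the
design with and without the contrast direction. Data splitting is what
makes these p-values honest: selection optimizes over directions and
thresholds, and re-testing the same cells inflates the type-I error (the
package's tests demonstrate the inflation directly).

### Small-sample calibration of the NB test

With only $\sim$6 pseudobulk samples, per-gene maximum-likelihood
dispersions are biased toward zero and a $\chi^2_1$ reference is strongly
anticonservative (we measured $\sim$9% of null genes below $p = 0.01$).
The test therefore (i) estimates dispersion from the Cox–Reid adjusted
profile likelihood, (ii) moderates it across genes by weighted likelihood
(each gene's profile is augmented with $\mathrm{priorDf}/\mathrm{df}$ times
the average profile; prior df 10), (iii) never lets a per-gene dispersion
fall below the common value — genes whose few samples happen to scatter
tightly would otherwise dominate the false discoveries — and (iv) refers
the LRT statistic to $F(1, \mathrm{df} + \mathrm{priorDf})$. These are the
standard small-sample devices of the pseudobulk count-testing tools this
module mirrors. Null calibration was verified on two regimes: i.i.d.
Gamma-Poisson counts (dispersion 0.2) and deep pseudobulks dominated by
log-normal per-sample effects. When raw counts are absent the pipeline
falls back to per-gene OLS on pseudobulk means with a t-test
(`lmTest()`), with a warning.

Genes with constant $\Delta$ get no neighborhood and `NA` p-values;
Benjamini–Hochberg adjustment runs across the tested genes.

# The benchmark simulator

`simulateBenchmarkCounts()` emulates the structure of semi-synthetic DE
benchmarks built on real data, without external data:

* a latent backbone $u_c \in \mathbb{R}^{10}$ from a 5-component Gaussian
  mixture (component means $\mathcal N(0, 1.5^2)$, within-component sd 0.5)
  stands in for cell-type/state structure; every gene loads on it
  ($w_g \sim \mathcal N(0, 0.3^2)$ per dimension), so "null" genes still
  carry cell-state signal, as real genes do;
* k-means partitions of the backbone with $k \in \{2, 3, 10, 20\}$ provide
  candidate affected groups; each implanted gene picks one cluster of one
  partition, with log2 fold changes $\{0.5, 1, 2, 4\}$ paired inversely
  with cluster size (finest partition, strongest effect);
* counts are Gamma-Poisson, $Y_{gc} \sim \mathrm{GP}(\mu = 2^{\eta_{gc}}
  \mathrm{sf}_c, \alpha = 0.2)$, with $\eta_{gc} = \beta^{(0)}_g + w_g^\top
  u_c + \beta^{(\mathrm{DE})}_g x^{(\mathrm{isDE})}_c +
  \beta^{(\mathrm{samp})}_{g,s(c)}$; the implanted indicator marks cluster
  cells in the treatment condition;
* per-sample random effects $\beta^{(\mathrm{samp})} \sim \mathcal N(0,
  0.1^2)$ and log-normal size factors (sd 0.25, normalized to mean 1)
  provide replicate-level and depth variation; baselines $\beta^{(0)}$ are
  $\mathcal N(1, 1.5^2)$ truncated to $[-2, 6]$, spanning realistic
  single-cell magnitudes. The baseline distribution and backbone geometry
  are this package's own stand-ins (the benchmarks they emulate used real
  expression matrices) and are configurable.

What the simulator does *not* reproduce: empirical mean–variance trends
across genes (dispersion is constant), dropout structure beyond
Gamma-Poisson sampling, non-Gaussian cluster shapes, and ambient/doublet
artifacts. Passing tests on it show correct behaviour of the machinery
under its stated assumptions, not performance guarantees on any particular
real dataset.

`makeToyTwoGene()` builds the minimal stylized case — two genes, two cell
groups on condition-specific one-dimensional subspaces, where gene 1 falls
under treatment only in the "left" group and gene 2 rises only in the
"right" group — the pattern a global or cluster-averaged test washes out.

# Evaluation metrics

`knnMixing()` (mean number of a cell's $k = 20$ nearest reference neighbors
sharing its condition; $k/2$ is ideal for balanced two-condition data),
`adjustedRandIndex()`, `fdpTpr()` (gene-level calls at a nominal BH
threshold), `labelCellGroups()` (the 60%/10% positive/negative rule with
largest-fraction fallback, for methods testing many groups per gene), and
`predictionL2Metrics()` ($L_2$ distance of mean and sd vectors, overall and
per cell type).

# Defaults and problem sizes

| parameter | default | rationale |
|---|---|---|
| latent dimension `nEmbedding` | 30 | standard operating point for this model family; the fit is closed-form, so the cost of a generous $P$ is small |
| `testFraction` | 0.5 | half the cells buy honest post-selection inference |
| `nDirections` | 100 | random one-dimensional projections; more directions sharpen neighborhoods at linear cost |
| `minCells` | 10 | below this, pseudobulks are too sparse to test |
| shifted-log pseudo-count | 1 | `log1p` of size-normalized counts |
| alignment $\lambda$ | 0.01/matched cell | scale-free pull toward identity |
| NB prior df | 10 | moderation strength; standard small-sample choice |
| nominal FDR | 0.1 | reporting threshold |

The package's replicate benchmarks run at 2,200 genes $\times$ 1,800 cells
(2 conditions $\times$ 3 samples $\times$ 300 cells) for FDR/power, and 800
genes $\times$ 900 cells for the pure-null splitting comparison — sizes
chosen so the whole suite completes in minutes on a single core while
keeping $\geq$ 90 cells in the smallest implanted clusters.

# Known limitations

* $\Delta$ is affine in the latent coordinates per contrast, so a sharply
  cluster-bounded effect is represented as a ramp; neighborhoods of weak,
  broad effects are systematically larger than the truly affected set, and
  their pseudobulk effect estimates are diluted.
* The base point, and with it the cross-condition correspondence, is a
  modelling convention (see above); counterfactual predictions inherit it.
* The neighborhood scan is stochastic through its random directions;
  results are reproducible only at fixed seed.
* Sample-level confounding (batch = condition) cannot be rescued by data
  splitting; with three replicates per condition the NB test absorbs
  sample effects through its dispersion, at a real cost in power.
* No uncertainty is attached to $\Delta$ or to neighborhood boundaries.
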