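# Two-stage differential co-expression between a discovery and a test
# condition: seven module-level topological statistics, a without-replacement
# node-label permutation null on the test side, Z-summary scoring, and a
# four-way preservation status.

PRESERVATION_STATS <- c("avg.weight", "coherence", "avg.cor", "avg.contrib",
                        "cor.cor", "cor.degree", "cor.contrib")
.DENSITY_STATS <- PRESERVATION_STATS[1:4]
.CONNECTIVITY_STATS <- PRESERVATION_STATS[5:7]

#' Pair a discovery and a test condition
#'
#' Binds two expression datasets and their network builds over the shared
#' gene universe; all preservation statistics are computed on
#' `module intersect sharedGenes`.
#'
#' @param discoveryData,testData [ExpressionDataset-class] objects.
#' @param discoveryBuild,testBuild matching [NetworkBuild-class] objects.
#' @return A [ConditionPair-class].
#' @export
conditionPair <- function(discoveryData, discoveryBuild, testData, testBuild) {
  stopifnot(identical(geneIds(discoveryData), geneIds(discoveryBuild)),
            identical(geneIds(testData), geneIds(testBuild)))
  shared <- intersect(geneIds(discoveryData), geneIds(testData))
  if (length(shared) == 0) stop("discovery and test share no genes")
  new("ConditionPair", discoveryData = discoveryData,
      discoveryBuild = discoveryBuild, testData = testData,
      testBuild = testBuild, sharedGenes = shared)
}

# precomputed shared-gene matrices for fast repeated statistic evaluation
.pairContext <- function(pair) {
  g <- pair@sharedGenes
  list(genes = g,
       ZD = .zscore(exprValues(pair@discoveryData)[, g, drop = FALSE]),
       ZT = .zscore(exprValues(pair@testData)[, g, drop = FALSE]),
       CD = correlationMatrix(pair@discoveryBuild)[g, g, drop = FALSE],
       CT = correlationMatrix(pair@testBuild)[g, g, drop = FALSE],
       WD = tomMatrix(pair@discoveryBuild)[g, g, drop = FALSE],
       WT = tomMatrix(pair@testBuild)[g, g, drop = FALSE])
}

# node contributions: correlation of each (z-scored) gene with the module
# summary profile h (itself zero-mean unit-variance)
.nodeContrib <- function(Z) {
  e <- .eigengeneFromZ(Z)$eigengene
  as.vector(crossprod(Z, e)) / (nrow(Z) - 1)
}

# discovery-side quantities that stay fixed across permutations
.moduleContext <- function(ctx, moduleGenes) {
  mg <- intersect(moduleGenes, ctx$genes)
  m <- length(mg)
  if (m < 3) stop("module has fewer than 3 genes in the shared universe")
  nuD <- .nodeContrib(ctx$ZD[, mg, drop = FALSE])
  wD <- ctx$WD[mg, mg]
  list(genes = mg, m = m, nuD = nuD,
       s = ifelse(nuD >= 0, 1, -1),
       kD = rowSums(wD) - 1,
       cDlow = .lowerTri(ctx$CD[mg, mg]))
}

# pairwise correlation that is exactly 1 on bitwise-identical inputs, so a
# self-comparison (test == discovery) reports cross-condition statistics of
# exactly 1 rather than 1 minus a rounding ulp
.corPair <- function(x, y) {
  if (identical(x, y)) return(1)
  .corQuiet(x, y)
}

# the seven statistics for an arbitrary test-side gene set of size m
.testStats <- function(ctx, modCtx, testGenes) {
  m <- modCtx$m
  s <- modCtx$s
  wT <- ctx$WT[testGenes, testGenes]
  cT <- ctx$CT[testGenes, testGenes]
  nuT <- .nodeContrib(ctx$ZT[, testGenes, drop = FALSE])
  denom <- m * (m - 1)
  c(avg.weight = (sum(wT) - m) / denom,
    coherence = mean(nuT^2),
    avg.cor = (as.numeric(crossprod(s, cT %*% s)) - m) / denom,
    avg.contrib = mean(nuT * s),
    cor.cor = .corPair(modCtx$cDlow, .lowerTri(cT)),
    cor.degree = .corPair(modCtx$kD, rowSums(wT) - 1),
    cor.contrib = .corPair(modCtx$nuD, nuT))
}

#' Seven module preservation statistics
#'
#' Computes, for one module, four density statistics on the test condition
#' (avg.weight: mean off-diagonal TOM weight; coherence: mean squared node
#' contribution; avg.cor and avg.contrib: mean correlation and mean node
#' contribution sign-anchored to the discovery-side node contributions) and
#' three cross-condition connectivity statistics (cor.cor: correlation of
#' off-diagonal correlations; cor.degree: correlation of intramodular TOM
#' degrees; cor.contrib: correlation of node contributions). Node
#' contributions are correlations of each gene with the module summary
#' profile (eigengene), computed per condition.
#'
#' @param pair a [ConditionPair-class].
#' @param moduleGenes character vector; statistics use
#'   `moduleGenes intersect sharedGenes(pair)` (>= 3 genes required).
#' @return Named numeric vector of the seven statistics; a statistic whose
#'   correlation input has zero variance is NaN.
#' @export
preservationStats <- function(pair, moduleGenes) {
  ctx <- .pairContext(pair)
  modCtx <- .moduleContext(ctx, moduleGenes)
  .testStats(ctx, modCtx, modCtx$genes)
}

.permPValues <- function(obs, perm, alternative) {
  vapply(seq_along(obs), function(j) {
    o <- obs[j]
    x <- perm[, j]
    x <- x[!is.na(x)]
    if (is.na(o) || length(x) == 0) return(NaN)
    hits <- if (alternative == "greater") sum(x >= o)
    else sum(abs(x - mean(x)) >= abs(o - mean(x)))
    (hits + 1) / (length(x) + 1)
  }, numeric(1))
}

#' Permutation null for the preservation statistics
#'
#' Each permutation draws `m` distinct genes uniformly (without replacement)
#' from the test-side shared-gene universe and substitutes them for the
#' module's genes on the test side only; discovery-side quantities (sign
#' anchors, intramodular degrees, node contributions) stay fixed. One-sided
#' ("greater") p-values use `(# perm >= obs + 1) / (nPerm + 1)`; two-sided
#' p-values compare distances from the permutation mean.
#'
#' @param pair a [ConditionPair-class].
#' @param moduleGenes the module's genes.
#' @param nPerm number of permutations (default 1000; < 100 warns).
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @param seed optional RNG seed; the null is fully determined by it.
#' @param excludeModule if TRUE, permutations draw only from genes outside
#'   the module (default FALSE: every shared gene is in the pool).
#' @return List with `observed`, `permMean`, `permSd`, `pValues` (each a
#'   named 7-vector), `nPerm` and `alternative`.
#' @export
permutationNull <- function(pair, moduleGenes, nPerm = 1000,
                            alternative = c("greater", "two_sided"),
                            seed = NULL, excludeModule = FALSE) {
  alternative <- match.arg(alternative)
  if (nPerm < 100) warning("fewer than 100 permutations; p-values are coarse",
                           call. = FALSE)
  ctx <- .pairContext(pair)
  modCtx <- .moduleContext(ctx, moduleGenes)
  pool <- if (excludeModule) setdiff(ctx$genes, modCtx$genes) else ctx$genes
  if (length(pool) <= modCtx$m)
    stop("shared-gene universe too small to draw ", modCtx$m, " distinct genes")
  if (!is.null(seed)) set.seed(seed)
  obs <- .testStats(ctx, modCtx, modCtx$genes)
  perm <- matrix(NA_real_, nPerm, length(PRESERVATION_STATS),
                 dimnames = list(NULL, PRESERVATION_STATS))
  for (b in seq_len(nPerm)) {
    perm[b, ] <- .testStats(ctx, modCtx, sample(pool, modCtx$m))
  }
  list(observed = obs,
       permMean = colMeans(perm, na.rm = TRUE),
       permSd = apply(perm, 2, stats::sd, na.rm = TRUE),
       pValues = stats::setNames(.permPValues(obs, perm, alternative),
                                 PRESERVATION_STATS),
       nPerm = as.integer(nPerm), alternative = alternative)
}

#' Z-summary from observed statistics and permutation summaries
#'
#' Per-statistic Z-scores `(obs - permMean) / permSd`; Z-density is the
#' median over the four density statistics, Z-connectivity the median over
#' the three connectivity statistics, and the Z-summary their mean. A
#' statistic with zero permutation spread gets a NaN Z and is excluded from
#' the medians; if a whole group is NaN the Z-summary is NaN.
#'
#' @param observed,permMean,permSd named 7-vectors (see [permutationNull()]).
#' @return List with `zScores`, `zDensity`, `zConnectivity`, `zSummary`.
#' @export
zSummaryScore <- function(observed, permMean, permSd) {
  z <- (observed - permMean) / permSd
  z[!is.finite(z)] <- NaN
  med <- function(v) { v <- v[!is.na(v)]; if (length(v) == 0) NaN else stats::median(v) }
  zd <- med(z[.DENSITY_STATS])
  zc <- med(z[.CONNECTIVITY_STATS])
  list(zScores = z, zDensity = zd, zConnectivity = zc,
       zSummary = (zd + zc) / 2)
}

#' Four-way preservation status
#'
#' A module is `preserved` when all seven permutation p-values fall below
#' `alpha`. Non-significance alone cannot establish unpreservation, so the
#' remaining modules are triaged by the Z-summary: below 2 `unpreserved`,
#' between 2 and 10 `moderately_preserved`, and 10 or above (or an undefined
#' Z-summary) `inconclusive`. This second stage is a reconstruction of the
#' published decision tree, which is only summarized in supplementary
#' material.
#'
#' @param pValues named 7-vector of permutation p-values.
#' @param alpha significance level (default 0.05).
#' @param zSummary the Z-summary score.
#' @return One of "preserved", "moderately_preserved", "unpreserved",
#'   "inconclusive".
#' @export
classifyPreservation <- function(pValues, alpha = 0.05, zSummary) {
  if (length(pValues) != length(PRESERVATION_STATS) || anyNA(pValues)) {
    warning("missing p-value(s); status is inconclusive", call. = FALSE)
    return("inconclusive")
  }
  if (all(pValues < alpha)) return("preserved")
  if (is.na(zSummary)) return("inconclusive")
  if (zSummary < 2) return("unpreserved")
  if (zSummary < 10) return("moderately_preserved")
  "inconclusive"
}

#' Module preservation between two conditions
#'
#' Runs the full two-stage preservation test for every real module of a
#' partition (module 0, the unassigned set, is excluded): observed
#' statistics, permutation null, Z-summary, and four-way status. The RNG for
#' module `i` is seeded with `seed + i`, so reruns with the same seed are
#' bit-identical and module results do not depend on evaluation order.
#' Modules with fewer than 3 shared genes, or as large as the shared
#' universe, are skipped with a warning.
#'
#' @param pair a [ConditionPair-class] (discovery = reference condition).
#' @param partition [ModulePartition-class] detected on the discovery side.
#' @param nPerm permutations per module (default 1000).
#' @param alpha significance level (default 0.05).
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @param seed integer base seed (default 1).
#' @return A [PreservationReport-class].
#' @export
compareConditions <- function(pair, partition, nPerm = 1000, alpha = 0.05,
                              alternative = c("greater", "two_sided"),
                              seed = 1L) {
  alternative <- match.arg(alternative)
  labels <- moduleLabels(partition)
  ids <- sort(unique(labels[labels > 0]))
  ctx <- .pairContext(pair)
  nS <- length(PRESERVATION_STATS)
  emptyMat <- function() matrix(NA_real_, length(ids), nS,
                                dimnames = list(as.character(ids),
                                                PRESERVATION_STATS))
  observed <- permMean <- permSd <- pValues <- zScores <- emptyMat()
  zD <- zC <- zS <- stats::setNames(rep(NA_real_, length(ids)),
                                    as.character(ids))
  status <- stats::setNames(rep("inconclusive", length(ids)),
                            as.character(ids))
  for (i in seq_along(ids)) {
    mod <- ids[i]
    mg <- intersect(names(labels)[labels == mod], ctx$genes)
    if (length(mg) < 3 || length(mg) >= length(ctx$genes)) {
      warning("module ", mod, " skipped (", length(mg),
              " shared genes)", call. = FALSE)
      next
    }
    modCtx <- .moduleContext(ctx, mg)
    set.seed(seed + mod)
    obs <- .testStats(ctx, modCtx, modCtx$genes)
    perm <- matrix(NA_real_, nPerm, nS,
                   dimnames = list(NULL, PRESERVATION_STATS))
    for (b in seq_len(nPerm)) {
      perm[b, ] <- .testStats(ctx, modCtx, sample(ctx$genes, modCtx$m))
    }
    pm <- colMeans(perm, na.rm = TRUE)
    ps <- apply(perm, 2, stats::sd, na.rm = TRUE)
    pv <- .permPValues(obs, perm, alternative)
    zz <- zSummaryScore(obs, pm, ps)
    observed[i, ] <- obs; permMean[i, ] <- pm; permSd[i, ] <- ps
    pValues[i, ] <- pv; zScores[i, ] <- zz$zScores
    zD[i] <- zz$zDensity; zC[i] <- zz$zConnectivity; zS[i] <- zz$zSummary
    status[i] <- classifyPreservation(
      stats::setNames(pv, PRESERVATION_STATS), alpha, zz$zSummary)
  }
  new("PreservationReport", statNames = PRESERVATION_STATS,
      observed = observed, permMean = permMean, permSd = permSd,
      pValues = pValues, zScores = zScores, zDensity = zD,
      zConnectivity = zC, zSummary = zS, status = status,
      nPerm = as.integer(nPerm), alpha = alpha, alternative = alternative,
      seed = as.integer(seed))
}

#' Co-expression difference matrix
#'
#' `D_ij = T^test_ij - T^discovery_ij` over the shared genes (optionally one
#' module): a positive entry means the gene pair gained co-expression in the
#' test condition, a negative entry means it lost co-expression. The matrix
#' is symmetric with zero diagonal. When a partition carrying the
#' discovery-side dendrogram is supplied, rows/columns follow the dendrogram
#' leaf order.
#'
#' @param pair a [ConditionPair-class].
#' @param moduleRestrict optional module id; requires `partition`.
#' @param partition optional [ModulePartition-class] (module restriction
#'   and/or dendrogram ordering).
#' @return Symmetric numeric matrix over the selected genes.
#' @export
coexpDifference <- function(pair, moduleRestrict = NULL, partition = NULL) {
  genes <- pair@sharedGenes
  if (!is.null(moduleRestrict)) {
    if (is.null(partition)) stop("module restriction requires a partition")
    labels <- moduleLabels(partition)
    sel <- names(labels)[labels == moduleRestrict]
    if (length(sel) == 0) stop("unknown module id: ", moduleRestrict)
    genes <- intersect(genes, sel)
  }
  if (length(genes) < 2) stop("fewer than 2 shared genes selected")
  if (!is.null(partition) && inherits(partition@dendrogram, "hclust")) {
    ord <- partition@dendrogram$labels[partition@dendrogram$order]
    genes <- ord[ord %in% genes]
  }
  d <- tomMatrix(pair@testBuild)[genes, genes] -
    tomMatrix(pair@discoveryBuild)[genes, genes]
  diag(d) <- 0
  d
}
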