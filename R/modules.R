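# Module detection: average-linkage clustering of TOM dissimilarity, a
# two-stage (static cut + kME assignment) dynamic tree cut, module
# eigengenes, and eigengene-based merging of highly correlated modules.

#' Hierarchical clustering of genes on TOM dissimilarity
#'
#' Average-linkage agglomerative clustering of `d_ij = 1 - T_ij`.
#'
#' @param tom a topological overlap matrix (symmetric, unit diagonal).
#' @return An `hclust` object with gene ids as labels.
#' @export
clusterGenes <- function(tom) {
  .checkSymmetric(tom, "tom")
  d <- stats::as.dist(1 - tom)
  stats::hclust(d, method = "average")
}

#' Two-stage dynamic tree cut
#'
#' Stage 1 cuts the dendrogram at `staticCutFraction` of its maximum merge
#' height; branches with at least `minModuleSize` genes become provisional
#' modules, everything else is provisionally unassigned. Stage 2 computes
#' provisional module eigengenes and assigns each provisionally unassigned
#' gene to the module maximizing |kME| when that |kME| reaches
#' `kmeAssignThreshold`; remaining genes get label 0 (unassigned). Final
#' modules are renumbered 1..M by decreasing size.
#'
#' This is a simplified hybrid variant of the dynamic tree cut family:
#' behavioral equivalence on well-separated modules, not algorithmic
#' equivalence, is the contract.
#'
#' @param dendrogram `hclust` from [clusterGenes()] on the same genes.
#' @param ds the [ExpressionDataset-class] the TOM was built from.
#' @param minModuleSize minimum branch size to seed a module (default 20).
#' @param staticCutFraction cut height as a fraction of the maximum merge
#'   height (default 0.99).
#' @param kmeAssignThreshold minimum |kME| for stage-2 assignment
#'   (default 0.30).
#' @return Named integer vector of labels (0 = unassigned).
#' @export
cutGeneTree <- function(dendrogram, ds, minModuleSize = 20,
                        staticCutFraction = 0.99, kmeAssignThreshold = 0.30) {
  if (minModuleSize < 2) stop("minModuleSize must be >= 2")
  genes <- dendrogram$labels
  cutHeight <- staticCutFraction * max(dendrogram$height)
  branch <- stats::cutree(dendrogram, h = cutHeight)
  sizes <- table(branch)
  keep <- as.integer(names(sizes)[sizes >= minModuleSize])
  labels <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_along(keep)) labels[branch == keep[i]] <- i
  # stage 2: kME-based assignment of provisionally unassigned genes
  if (length(keep) > 0 && any(labels == 0)) {
    E <- vapply(seq_along(keep), function(i) {
      computeEigengene(ds, names(labels)[labels == i])$eigengene
    }, numeric(nrow(exprValues(ds))))
    unassigned <- names(labels)[labels == 0]
    km <- .corQuiet(exprValues(ds)[, unassigned, drop = FALSE], E)
    best <- max.col(abs(km), ties.method = "first")
    bestVal <- abs(km)[cbind(seq_along(best), best)]
    hit <- !is.na(bestVal) & bestVal >= kmeAssignThreshold
    labels[unassigned[hit]] <- best[hit]
  }
  .relabelBySize(labels)
}

#' Module eigengene
#'
#' First principal component of the module's per-gene z-scored expression,
#' scaled to unit variance. The sign is anchored so that the eigengene
#' correlates non-negatively with the module's mean z-scored expression,
#' making results reproducible across runs and platforms.
#'
#' @param ds an [ExpressionDataset-class].
#' @param genes character vector of member gene ids (>= 1).
#' @return A list with `eigengene` (named numeric over samples, unit
#'   variance) and `explainedVariance` (fraction lambda_1 / sum lambda).
#' @export
computeEigengene <- function(ds, genes) {
  if (length(genes) < 1) stop("need >= 1 gene")
  m <- exprValues(ds)
  missing <- setdiff(genes, colnames(m))
  if (length(missing) > 0)
    stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  Z <- .zscore(m[, genes, drop = FALSE])
  res <- .eigengeneFromZ(Z)
  list(eigengene = stats::setNames(res$eigengene, rownames(m)),
       explainedVariance = res$explainedVariance)
}

# core eigengene computation on an already z-scored matrix (samples x genes)
.eigengeneFromZ <- function(Z) {
  sv <- svd(Z, nu = 1, nv = 0)
  e <- sv$u[, 1] * sv$d[1]
  s <- stats::sd(e)
  if (s > 0) e <- e / s
  anchor <- suppressWarnings(stats::cor(e, rowMeans(Z)))
  if (is.na(anchor)) anchor <- suppressWarnings(stats::cor(e, Z[, 1]))
  if (!is.na(anchor) && anchor < 0) e <- -e
  list(eigengene = e, explainedVariance = sv$d[1]^2 / sum(sv$d^2))
}

.moduleEigengenes <- function(ds, labels) {
  ids <- sort(unique(labels[labels > 0]))
  n <- nrow(exprValues(ds))
  E <- matrix(numeric(0), nrow = n, ncol = 0,
              dimnames = list(sampleIds(ds), NULL))
  if (length(ids) > 0) {
    E <- vapply(ids, function(i) {
      computeEigengene(ds, names(labels)[labels == i])$eigengene
    }, numeric(n))
    dimnames(E) <- list(sampleIds(ds), paste0("ME", ids))
  }
  E
}

#' Merge highly correlated modules
#'
#' Iteratively merges the pair of modules whose eigengenes are most
#' correlated while `1 - cor` is at most `mergeCut` (default 0.25, i.e.
#' eigengene correlation >= 0.75), recomputing eigengenes after every merge.
#' Merging makes the partition robust to over-splitting by the tree cut.
#'
#' @param ds an [ExpressionDataset-class].
#' @param labels named integer labels from [cutGeneTree()].
#' @param mergeCut eigengene dissimilarity threshold in [0, 2].
#' @param dendrogram optional `hclust` to store in the result.
#' @return A [ModulePartition-class] with final labels renumbered by
#'   decreasing size, eigengenes, the full kME matrix, pre-merge labels and
#'   the merge history (in pre-merge label space).
#' @export
mergeCloseModules <- function(ds, labels, mergeCut = 0.25, dendrogram = NULL) {
  if (mergeCut < 0 || mergeCut > 2) stop("mergeCut must lie in [0, 2]")
  labelsPremerge <- labels
  history <- data.frame(absorbed = integer(0), surviving = integer(0),
                        eigengene_cor = numeric(0))
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) < 2) break
    E <- vapply(ids, function(i) {
      computeEigengene(ds, names(labels)[labels == i])$eigengene
    }, numeric(nrow(exprValues(ds))))
    C <- .corQuiet(E)
    diag(C) <- -Inf
    idx <- which(C == max(C), arr.ind = TRUE)[1, ]
    maxCor <- C[idx[1], idx[2]]
    if (!is.finite(maxCor) || 1 - maxCor > mergeCut) break
    a <- ids[idx[1]]; b <- ids[idx[2]]
    sa <- sum(labels == a); sb <- sum(labels == b)
    surviving <- if (sa > sb || (sa == sb && a < b)) a else b
    absorbed <- if (surviving == a) b else a
    labels[labels == absorbed] <- surviving
    history <- rbind(history,
                     data.frame(absorbed = absorbed, surviving = surviving,
                                eigengene_cor = maxCor))
  }
  labels <- .relabelBySize(labels)
  E <- .moduleEigengenes(ds, labels)
  km <- if (ncol(E) > 0) .corQuiet(exprValues(ds), E) else
    matrix(numeric(0), nrow = ncol(exprValues(ds)), ncol = 0,
           dimnames = list(geneIds(ds), NULL))
  new("ModulePartition", labels = labels, labelsPremerge = labelsPremerge,
      dendrogram = dendrogram, eigengenes = E, kme = km,
      mergeHistory = history)
}

#' Detect co-expression modules
#'
#' Composes [clusterGenes()], [cutGeneTree()] and [mergeCloseModules()]:
#' hierarchical clustering of TOM dissimilarity, two-stage dynamic tree cut,
#' and eigengene-based merging. Returns the final partition together with the
#' dendrogram and the pre-merge labels.
#'
#' @param ds the [ExpressionDataset-class] the network was built from.
#' @param build a [NetworkBuild-class] on the same genes.
#' @param minModuleSize,staticCutFraction,kmeAssignThreshold passed to
#'   [cutGeneTree()].
#' @param mergeCut passed to [mergeCloseModules()].
#' @return A [ModulePartition-class].
#' @examples
#' sim <- simulateExpression(simulationConfig(50, moduleSizes = c(30, 30),
#'                                            nBackground = 40, seed = 11))
#' net <- buildNet(sim$dataset, power = 6)
#' mp <- detectModules(sim$dataset, net)
#' moduleSizes(mp)
#' @export
detectModules <- function(ds, build, minModuleSize = 20,
                          staticCutFraction = 0.99, kmeAssignThreshold = 0.30,
                          mergeCut = 0.25) {
  stopifnot(identical(geneIds(build), geneIds(ds)))
  dendro <- clusterGenes(tomMatrix(build))
  labels <- cutGeneTree(dendro, ds, minModuleSize, staticCutFraction,
                        kmeAssignThreshold)
  mergeCloseModules(ds, labels, mergeCut, dendrogram = dendro)
}

#' Plot a module's expression profiles
#'
#' Minimal per-module profile plot: the z-scored expression of every member
#' gene across samples (grey), with the module eigengene highlighted.
#'
#' @param ds an [ExpressionDataset-class].
#' @param partition a [ModulePartition-class].
#' @param moduleId module to plot.
#' @return The eigengene, invisibly.
#' @export
plotModuleProfile <- function(ds, partition, moduleId) {
  labels <- moduleLabels(partition)
  genes <- names(labels)[labels == moduleId]
  if (length(genes) == 0) stop("unknown or empty module: ", moduleId)
  Z <- .zscore(exprValues(ds)[, genes, drop = FALSE])
  e <- eigengenes(partition)[, paste0("ME", moduleId)]
  graphics::matplot(Z, type = "l", lty = 1, col = grDevices::grey(0.8),
                    xlab = "sample", ylab = "z-scored expression",
                    main = paste("Module", moduleId))
  graphics::lines(e, col = "red3", lwd = 2)
  invisible(e)
}
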