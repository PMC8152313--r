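#' @import methods
NULL

# ---------------------------------------------------------------------------
# ExpressionDataset
# ---------------------------------------------------------------------------

#' Expression dataset (samples x genes)
#'
#' Container for a normalized expression matrix with samples as rows and genes
#' as columns. All downstream steps of the pipeline (filtering, network
#' construction, module detection, differential co-expression) consume this
#' class. Values must be finite; identifiers must be unique.
#'
#' @slot values numeric matrix, samples x genes, with rownames (sample ids)
#'   and colnames (gene ids).
#'
#' @seealso [readExpression()], [simulateExpression()]
#' @export
setClass("ExpressionDataset", representation(values = "matrix"))

setValidity("ExpressionDataset", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 2 || ncol(v) < 2) return("need at least 2 samples and 2 genes")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry sample ids (rownames) and gene ids (colnames)")
  if (anyDuplicated(rownames(v))) return("duplicate sample ids")
  if (anyDuplicated(colnames(v))) return("duplicate gene ids")
  if (!all(is.finite(v))) return("all values must be finite (no NA/NaN/Inf)")
  TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of normalized expression, samples x rows
#'   orientation given by `sampleIds`/`geneIds` or dimnames.
#' @param sampleIds,geneIds optional character vectors overriding dimnames.
#' @return An [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' ExpressionDataset(m)
#' @export
ExpressionDataset <- function(values, sampleIds = NULL, geneIds = NULL) {
  if (!is.null(sampleIds)) rownames(values) <- sampleIds
  if (!is.null(geneIds)) colnames(values) <- geneIds
  new("ExpressionDataset", values = values)
}

#' @describeIn ExpressionDataset-class expression matrix (samples x genes)
#' @param x,object an `ExpressionDataset`
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @export
setMethod("exprValues", "ExpressionDataset", function(x) x@values)

#' @describeIn ExpressionDataset-class sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) rownames(x@values))

#' @describeIn ExpressionDataset-class gene identifiers
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) colnames(x@values))

#' @export
setMethod("dim", "ExpressionDataset", function(x) dim(x@values))

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset:", nrow(object@values), "samples x",
      ncol(object@values), "genes\n")
})

# ---------------------------------------------------------------------------
# GeneSetCollection (GMT)
# ---------------------------------------------------------------------------

#' Gene set collection (GMT)
#'
#' A list of annotation terms, each a non-empty set of gene identifiers, as
#' read from a Gene Matrix Transposed (GMT) file. Used as the reference for
#' local over-representation analysis.
#'
#' @slot genes named list of character vectors (one set per term id).
#' @slot descriptions named character vector of term descriptions.
#' @seealso [readGMT()], [oraEnrich()]
#' @export
setClass("GeneSetCollection",
         representation(genes = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  ids <- names(object@genes)
  if (is.null(ids) || anyDuplicated(ids)) return("term ids must be unique")
  if (any(lengths(object@genes) == 0)) return("every term must have >= 1 gene")
  if (!identical(names(object@descriptions), ids))
    return("descriptions must be named by the same term ids")
  TRUE
})

#' Construct a GeneSetCollection
#' @param genes named list of character vectors of gene ids.
#' @param descriptions optional named character vector of descriptions.
#' @export
GeneSetCollection <- function(genes, descriptions = NULL) {
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(genes)), names(genes))
  }
  new("GeneSetCollection", genes = genes,
      descriptions = descriptions[names(genes)])
}

#' @describeIn GeneSetCollection-class term ids
#' @param x a `GeneSetCollection`
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @export
setMethod("termIds", "GeneSetCollection", function(x) names(x@genes))

#' @describeIn GeneSetCollection-class named list of gene sets
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@genes)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@genes))

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@genes), "terms,",
      length(unique(unlist(object@genes))), "distinct genes\n")
})

# ---------------------------------------------------------------------------
# NetworkBuild
# ---------------------------------------------------------------------------

#' Co-expression network build
#'
#' The carrier of the co-expression score: gene-gene correlation, the fitted
#' soft-threshold power, the adjacency matrix `|r|^beta`, and the topological
#' overlap matrix (TOM), together with provenance metadata. Networks are
#' unsigned.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot corMethod "pearson" or "spearman".
#' @slot networkType always "unsigned".
#' @slot correlation symmetric correlation matrix in [-1, 1], unit diagonal.
#' @slot power the soft-threshold exponent beta (integer >= 1).
#' @slot fitTable data.frame of the scale-free fit per candidate power.
#' @slot adjacency symmetric matrix `|r|^beta` in [0, 1], unit diagonal.
#' @slot tom symmetric topological overlap matrix in [0, 1], unit diagonal.
#' @slot metadata list of the parameters used (provenance).
#' @seealso [buildNet()], [tomFromAdjacency()]
#' @export
setClass("NetworkBuild",
         representation(geneIds = "character", corMethod = "character",
                        networkType = "character", correlation = "matrix",
                        power = "numeric", fitTable = "data.frame",
                        adjacency = "matrix", tom = "matrix",
                        metadata = "list"))

setValidity("NetworkBuild", function(object) {
  n <- length(object@geneIds)
  for (nm in c("correlation", "adjacency", "tom")) {
    m <- slot(object, nm)
    if (!.isSquare(m) || nrow(m) != n)
      return(sprintf("%s must be %d x %d", nm, n, n))
    if (max(abs(m - t(m))) > 1e-8) return(paste(nm, "must be symmetric"))
    if (max(abs(diag(m) - 1)) > 1e-8) return(paste(nm, "must have unit diagonal"))
  }
  if (min(object@correlation) < -1 - 1e-8 || max(object@correlation) > 1 + 1e-8)
    return("correlation entries must lie in [-1, 1]")
  if (min(object@adjacency) < -1e-12 || min(object@tom) < -1e-12 ||
      max(object@adjacency) > 1 + 1e-8 || max(object@tom) > 1 + 1e-8)
    return("adjacency/tom entries must lie in [0, 1]")
  if (object@power < 1) return("power must be >= 1")
  if (!object@networkType %in% "unsigned") return("networkType must be 'unsigned'")
  TRUE
})

#' @describeIn NetworkBuild-class the topological overlap matrix
#' @param x a `NetworkBuild`
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))
#' @export
setMethod("tomMatrix", "NetworkBuild", function(x) x@tom)

#' @describeIn NetworkBuild-class the adjacency matrix
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @export
setMethod("adjacencyMatrix", "NetworkBuild", function(x) x@adjacency)

#' @describeIn NetworkBuild-class the correlation matrix
#' @export
setGeneric("correlationMatrix", function(x) standardGeneric("correlationMatrix"))
#' @export
setMethod("correlationMatrix", "NetworkBuild", function(x) x@correlation)

#' @describeIn NetworkBuild-class the chosen soft-threshold power
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))
#' @export
setMethod("softPower", "NetworkBuild", function(x) x@power)

#' @describeIn NetworkBuild-class scale-free fit table per candidate power
#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))
#' @export
setMethod("fitTable", "NetworkBuild", function(x) x@fitTable)

#' @export
setMethod("geneIds", "NetworkBuild", function(x) x@geneIds)

#' @describeIn NetworkBuild-class provenance metadata list
#' @export
setGeneric("buildMetadata", function(x) standardGeneric("buildMetadata"))
#' @export
setMethod("buildMetadata", "NetworkBuild", function(x) x@metadata)

setMethod("show", "NetworkBuild", function(object) {
  cat("NetworkBuild:", length(object@geneIds), "genes |",
      object@corMethod, "correlation | unsigned | power =", object@power, "\n")
})

# ---------------------------------------------------------------------------
# ModulePartition
# ---------------------------------------------------------------------------

#' Module partition
#'
#' Result of module detection: gene labels (0 = unassigned, real modules
#' numbered 1..M by decreasing size), the pre-merge labels, the gene
#' dendrogram, module eigengenes (first principal component of each module's
#' z-scored expression), the kME (module membership) matrix, and the merge
#' history.
#'
#' @slot labels named integer vector, gene id -> module (0 = unassigned).
#' @slot labelsPremerge same, before eigengene-based merging.
#' @slot dendrogram the `hclust` object of the gene clustering (or NULL).
#' @slot eigengenes samples x modules matrix, columns "ME1".."MEM".
#' @slot kme genes x modules matrix of cor(gene, eigengene).
#' @slot mergeHistory data.frame (absorbed, surviving, eigengene_cor).
#' @seealso [detectModules()], [mergeCloseModules()]
#' @export
setClass("ModulePartition",
         representation(labels = "integer", labelsPremerge = "integer",
                        dendrogram = "ANY", eigengenes = "matrix",
                        kme = "matrix", mergeHistory = "data.frame"))

setValidity("ModulePartition", function(object) {
  lab <- object@labels
  if (is.null(names(lab))) return("labels must be named by gene id")
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) > 0 && !identical(ids, seq_along(ids)))
    return("module ids must be 1..M (0 reserved for unassigned)")
  if (length(ids) > 0) {
    sizes <- vapply(ids, function(i) sum(lab == i), integer(1))
    if (is.unsorted(rev(sizes), strictly = FALSE))
      return("module ids must be ordered by decreasing size")
    if (ncol(object@eigengenes) != length(ids))
      return("one eigengene column per module required")
    vr <- apply(object@eigengenes, 2, stats::var)
    if (any(abs(vr - 1) > 1e-6)) return("eigengenes must have unit variance")
  }
  if (length(object@labelsPremerge) != length(lab))
    return("labelsPremerge must cover the same genes")
  TRUE
})

#' @describeIn ModulePartition-class gene -> module labels (0 = unassigned)
#' @param x a `ModulePartition`
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @export
setMethod("moduleLabels", "ModulePartition", function(x) x@labels)

#' @describeIn ModulePartition-class labels before eigengene merging
#' @export
setGeneric("moduleLabelsPremerge", function(x) standardGeneric("moduleLabelsPremerge"))
#' @export
setMethod("moduleLabelsPremerge", "ModulePartition", function(x) x@labelsPremerge)

#' @describeIn ModulePartition-class samples x modules eigengene matrix
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @export
setMethod("eigengenes", "ModulePartition", function(x) x@eigengenes)

#' @describeIn ModulePartition-class genes x modules kME matrix
#' @export
setGeneric("kme", function(x) standardGeneric("kme"))
#' @export
setMethod("kme", "ModulePartition", function(x) x@kme)

#' @describeIn ModulePartition-class named vector of module sizes (incl. 0)
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))
#' @export
setMethod("moduleSizes", "ModulePartition", function(x) {
  tab <- table(factor(x@labels, levels = sort(unique(x@labels))))
  stats::setNames(as.integer(tab), names(tab))
})

#' @describeIn ModulePartition-class merge history data.frame
#' @export
setGeneric("mergeHistory", function(x) standardGeneric("mergeHistory"))
#' @export
setMethod("mergeHistory", "ModulePartition", function(x) x@mergeHistory)

#' @describeIn ModulePartition-class the gene clustering dendrogram (hclust)
#' @export
setGeneric("geneDendrogram", function(x) standardGeneric("geneDendrogram"))
#' @export
setMethod("geneDendrogram", "ModulePartition", function(x) x@dendrogram)

setMethod("show", "ModulePartition", function(object) {
  nm <- max(object@labels, 0)
  cat("ModulePartition:", nm, "modules,",
      sum(object@labels == 0), "unassigned genes of", length(object@labels), "\n")
})

# ---------------------------------------------------------------------------
# GraphView / HubResult / SubModulePartition
# ---------------------------------------------------------------------------

#' Thresholded graph view of a co-expression network
#'
#' An undirected weighted graph keeping only edges whose TOM weight reaches
#' `edgeMin` (co-expression networks are complete graphs; an edge filter is
#' needed for any topological display or degree-type metric). The full TOM of
#' the retained vertex set is kept so threshold-independent metrics
#' (connectivity) stay available.
#'
#' @slot geneIds vertex gene ids (isolated vertices retained).
#' @slot edges data.frame (gene_a, gene_b, weight), gene_a < gene_b.
#' @slot edgeMin absolute TOM threshold in [0, 1].
#' @slot tom TOM submatrix over `geneIds`.
#' @seealso [graphFrom()], [nodeMetrics()]
#' @export
setClass("GraphView",
         representation(geneIds = "character", edges = "data.frame",
                        edgeMin = "numeric", tom = "matrix"))

setValidity("GraphView", function(object) {
  e <- object@edges
  if (!all(c("gene_a", "gene_b", "weight") %in% colnames(e)))
    return("edges must have columns gene_a, gene_b, weight")
  if (nrow(e) > 0) {
    if (any(e$gene_a >= e$gene_b)) return("edges must satisfy gene_a < gene_b")
    if (any(e$weight < object@edgeMin - 1e-12 | e$weight > 1 + 1e-12))
      return("edge weights must lie in [edgeMin, 1]")
  }
  TRUE
})

#' @export
setMethod("geneIds", "GraphView", function(x) x@geneIds)

#' @describeIn GraphView-class the retained edge table
#' @param x a `GraphView`
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @export
setMethod("graphEdges", "GraphView", function(x) x@edges)

setMethod("show", "GraphView", function(object) {
  cat("GraphView:", length(object@geneIds), "vertices,", nrow(object@edges),
      "edges (TOM >=", object@edgeMin, ")\n")
})

#' Hub detection result
#'
#' @slot method one of "connectivity", "degree", "kleinberg".
#' @slot scores named numeric vector of hub scores per gene.
#' @slot hubs character vector of selected hub genes.
#' @slot selectionRule list of the parameters that determined the selection.
#' @seealso [hubsConnectivity()], [hubsDegree()], [hubsKleinberg()]
#' @export
setClass("HubResult",
         representation(method = "character", scores = "numeric",
                        hubs = "character", selectionRule = "list"))

setValidity("HubResult", function(object) {
  if (!all(object@hubs %in% names(object@scores)))
    return("hubs must be a subset of scored genes")
  TRUE
})

#' @describeIn HubResult-class hub scores per gene
#' @param x a `HubResult`
#' @export
setGeneric("hubScores", function(x) standardGeneric("hubScores"))
#' @export
setMethod("hubScores", "HubResult", function(x) x@scores)

#' @describeIn HubResult-class selected hub genes
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))
#' @export
setMethod("hubGenes", "HubResult", function(x) x@hubs)

setMethod("show", "HubResult", function(object) {
  cat("HubResult (", object@method, "): ", length(object@hubs), " hubs of ",
      length(object@scores), " genes\n", sep = "")
})

#' Sub-module partition of one module
#'
#' PAM (k-medoids) clustering of a module on TOM dissimilarity, with the
#' number of sub-modules chosen by the mean silhouette width; `k = 1` means no
#' reliable substructure was found (silhouette below the floor, or module too
#' small).
#'
#' @slot moduleId module analysed.
#' @slot k chosen number of sub-modules.
#' @slot subLabels named integer vector gene -> 1..k.
#' @slot silhouetteByK named numeric, mean silhouette width per candidate k.
#' @slot medoids medoid gene per sub-module.
#' @seealso [detectSubmodules()]
#' @export
setClass("SubModulePartition",
         representation(moduleId = "integer", k = "integer",
                        subLabels = "integer", silhouetteByK = "numeric",
                        medoids = "character"))

setValidity("SubModulePartition", function(object) {
  if (object@k < 1) return("k must be >= 1")
  if (length(object@subLabels) > 0 && max(object@subLabels) != object@k)
    return("subLabels must cover 1..k")
  TRUE
})

#' @describeIn SubModulePartition-class gene -> sub-module labels
#' @param x a `SubModulePartition`
#' @export
setGeneric("subModuleLabels", function(x) standardGeneric("subModuleLabels"))
#' @export
setMethod("subModuleLabels", "SubModulePartition", function(x) x@subLabels)

#' @describeIn SubModulePartition-class mean silhouette width per candidate k
#' @export
setGeneric("silhouetteByK", function(x) standardGeneric("silhouetteByK"))
#' @export
setMethod("silhouetteByK", "SubModulePartition", function(x) x@silhouetteByK)

setMethod("show", "SubModulePartition", function(object) {
  cat("SubModulePartition: module", object@moduleId, "->", object@k,
      "sub-modules\n")
})

# ---------------------------------------------------------------------------
# ConditionPair / PreservationReport
# ---------------------------------------------------------------------------

#' Discovery/test condition pair
#'
#' Two expression datasets with their network builds over a shared gene
#' universe; the input to module preservation testing and the co-expression
#' difference matrix.
#'
#' @slot discoveryData,testData [ExpressionDataset-class] objects.
#' @slot discoveryBuild,testBuild [NetworkBuild-class] objects.
#' @slot sharedGenes intersection of the two gene universes.
#' @seealso [conditionPair()], [compareConditions()], [coexpDifference()]
#' @export
setClass("ConditionPair",
         representation(discoveryData = "ExpressionDataset",
                        discoveryBuild = "NetworkBuild",
                        testData = "ExpressionDataset",
                        testBuild = "NetworkBuild",
                        sharedGenes = "character"))

setValidity("ConditionPair", function(object) {
  if (length(object@sharedGenes) < 2)
    return("discovery and test must share at least 2 genes")
  TRUE
})

#' @describeIn ConditionPair-class genes shared by both conditions
#' @param x a `ConditionPair`
#' @export
setGeneric("sharedGenes", function(x) standardGeneric("sharedGenes"))
#' @export
setMethod("sharedGenes", "ConditionPair", function(x) x@sharedGenes)

setMethod("show", "ConditionPair", function(object) {
  cat("ConditionPair:", length(object@sharedGenes), "shared genes |",
      nrow(exprValues(object@discoveryData)), "discovery samples,",
      nrow(exprValues(object@testData)), "test samples\n")
})

#' Module preservation report
#'
#' Per-module results of the two-stage differential co-expression test: the
#' seven observed topological statistics, their permutation-null summaries and
#' p-values, per-statistic Z-scores, the Z-density / Z-connectivity medians,
#' the Z-summary, and the four-way status.
#'
#' @slot statNames the seven statistic names (4 density + 3 connectivity).
#' @slot observed,permMean,permSd,pValues,zScores modules x 7 matrices.
#' @slot zDensity,zConnectivity,zSummary named numeric vectors per module.
#' @slot status named character: preserved, moderately_preserved, unpreserved,
#'   or inconclusive.
#' @slot nPerm,alpha,alternative,seed test parameters.
#' @seealso [compareConditions()], [classifyPreservation()]
#' @export
setClass("PreservationReport",
         representation(statNames = "character", observed = "matrix",
                        permMean = "matrix", permSd = "matrix",
                        pValues = "matrix", zScores = "matrix",
                        zDensity = "numeric", zConnectivity = "numeric",
                        zSummary = "numeric", status = "character",
                        nPerm = "integer", alpha = "numeric",
                        alternative = "character", seed = "integer"))

#' @describeIn PreservationReport-class four-way status per module
#' @param x a `PreservationReport`
#' @export
setGeneric("preservationStatus", function(x) standardGeneric("preservationStatus"))
#' @export
setMethod("preservationStatus", "PreservationReport", function(x) x@status)

#' @describeIn PreservationReport-class Z-summary per module
#' @export
setGeneric("zSummaryScores", function(x) standardGeneric("zSummaryScores"))
#' @export
setMethod("zSummaryScores", "PreservationReport", function(x) x@zSummary)

#' @describeIn PreservationReport-class observed statistics (modules x 7)
#' @export
setGeneric("observedStats", function(x) standardGeneric("observedStats"))
#' @export
setMethod("observedStats", "PreservationReport", function(x) x@observed)

#' @describeIn PreservationReport-class permutation p-values (modules x 7)
#' @export
setGeneric("permPValues", function(x) standardGeneric("permPValues"))
#' @export
setMethod("permPValues", "PreservationReport", function(x) x@pValues)

setMethod("show", "PreservationReport", function(object) {
  cat("PreservationReport:", nrow(object@observed), "modules |",
      object@nPerm, "permutations | alpha =", object@alpha, "\n")
  print(table(object@status))
})

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Synthetic expression simulation configuration
#'
#' Parameters of the planted-module factor model used to generate synthetic
#' expression data: each module m has a latent factor f_m ~ N(0,1) over
#' samples and member genes x = beta*f + sqrt(1-beta^2)*eps + noiseSd*eta;
#' background genes are pure standard normal noise. Per-module perturbations
#' ("none", "rewire", "destroy") define the test condition of a simulated
#' condition pair.
#'
#' @slot nSamples number of samples.
#' @slot moduleSizes integer vector of planted module sizes (may be empty).
#' @slot nBackground number of unstructured background genes.
#' @slot coherence per-module loading beta, strictly in (0, 1).
#' @slot noiseSd additional per-gene noise standard deviation (>= 0).
#' @slot perturbation per-module: "none", "rewire" or "destroy".
#' @slot rewireFraction per-module fraction of genes replaced under "rewire".
#' @slot seed RNG seed.
#' @seealso [simulationConfig()], [simulateExpression()],
#'   [simulateConditionPair()]
#' @export
setClass("SimulationConfig",
         representation(nSamples = "integer", moduleSizes = "integer",
                        nBackground = "integer", coherence = "numeric",
                        noiseSd = "numeric", perturbation = "character",
                        rewireFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nSamples < 2) return("nSamples must be >= 2")
  if (sum(object@moduleSizes) + object@nBackground < 2)
    return("need at least 2 genes in total")
  if (length(object@moduleSizes) > 0) {
    if (any(object@moduleSizes < 1)) return("module sizes must be >= 1")
    if (length(object@coherence) != length(object@moduleSizes) ||
        any(object@coherence <= 0) || any(object@coherence >= 1))
      return("coherence must be strictly in (0, 1), one value per module")
    if (length(object@perturbation) != length(object@moduleSizes) ||
        !all(object@perturbation %in% c("none", "rewire", "destroy")))
      return("perturbation must be none/rewire/destroy, one per module")
    if (any(object@rewireFraction < 0 | object@rewireFraction > 1))
      return("rewireFraction must lie in [0, 1]")
  }
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Construct a SimulationConfig
#'
#' @param nSamples number of samples.
#' @param moduleSizes integer vector of planted module sizes.
#' @param nBackground number of pure-noise background genes.
#' @param coherence factor loading beta in (0, 1); recycled over modules.
#' @param noiseSd additional noise standard deviation.
#' @param perturbation "none", "rewire" or "destroy"; recycled over modules.
#' @param rewireFraction fraction of member genes replaced under "rewire";
#'   recycled over modules.
#' @param seed RNG seed (integer).
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(60, moduleSizes = c(50, 30), nBackground = 100)
#' @export
simulationConfig <- function(nSamples, moduleSizes = integer(0),
                             nBackground = 0L, coherence = 0.8, noiseSd = 0.2,
                             perturbation = "none", rewireFraction = 0,
                             seed = 1L) {
  k <- length(moduleSizes)
  new("SimulationConfig",
      nSamples = as.integer(nSamples),
      moduleSizes = as.integer(moduleSizes),
      nBackground = as.integer(nBackground),
      coherence = if (k) rep_len(coherence, k) else numeric(0),
      noiseSd = as.numeric(noiseSd),
      perturbation = if (k) rep_len(perturbation, k) else character(0),
      rewireFraction = if (k) rep_len(rewireFraction, k) else numeric(0),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples,",
      length(object@moduleSizes), "planted modules (",
      paste(object@moduleSizes, collapse = ", "), ") +",
      object@nBackground, "background genes\n")
})

# ---------------------------------------------------------------------------
# FilterReport
# ---------------------------------------------------------------------------

#' Gene filter report
#'
#' @slot nIn,nOut gene counts before and after filtering.
#' @slot removedIds gene ids removed.
#' @slot filterKind "low_count" or "low_variation".
#' @slot parameters named list of the filter parameters.
#' @seealso [filterLowCounts()], [filterLowVariation()]
#' @export
setClass("FilterReport",
         representation(nIn = "integer", nOut = "integer",
                        removedIds = "character", filterKind = "character",
                        parameters = "list"))

setValidity("FilterReport", function(object) {
  if (object@nOut != object@nIn - length(object@removedIds))
    return("nOut must equal nIn - |removedIds|")
  TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport (", object@filterKind, "): ", object@nIn, " -> ",
      object@nOut, " genes\n", sep = "")
})
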