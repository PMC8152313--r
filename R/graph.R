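# Graph topology: thresholded graph views, node metrics, three hub-detection
# methods, and PAM + silhouette sub-module detection.

#' Thresholded graph view of a network build
#'
#' Co-expression networks are complete weighted graphs; any topological
#' display or degree-type metric needs an edge filter. Keeps all edges with
#' TOM weight at least `edgeMin` (absolute threshold), optionally restricted
#' to one module's genes; isolated vertices are retained.
#'
#' @param build a [NetworkBuild-class].
#' @param edgeMin absolute TOM threshold in [0, 1] (default 0).
#' @param moduleRestrict optional module id; requires `partition`.
#' @param partition [ModulePartition-class] when restricting to a module.
#' @return A [GraphView-class].
#' @export
graphFrom <- function(build, edgeMin = 0, moduleRestrict = NULL,
                      partition = NULL) {
  if (edgeMin < 0 || edgeMin > 1) stop("edgeMin must lie in [0, 1]")
  tom <- tomMatrix(build)
  if (!is.null(moduleRestrict)) {
    if (is.null(partition)) stop("module restriction requires a partition")
    labels <- moduleLabels(partition)
    genes <- names(labels)[labels == moduleRestrict]
    if (length(genes) == 0) stop("unknown module id: ", moduleRestrict)
    tom <- tom[genes, genes, drop = FALSE]
  }
  new("GraphView", geneIds = colnames(tom), edges = .edgeTable(tom, edgeMin),
      edgeMin = edgeMin, tom = tom)
}

#' Per-gene topological metrics
#'
#' Degree and strength depend on the edge filter; connectivity
#' `k_i = sum_{j != i} T_ij` is threshold-independent so it can be compared
#' across conditions without depending on the display filter.
#'
#' @param g a [GraphView-class].
#' @return data.frame with columns gene, degree (retained edge count),
#'   connectivity (sum of TOM weights to all other genes in the view) and
#'   strength (sum of retained edge weights).
#' @export
nodeMetrics <- function(g) {
  genes <- g@geneIds
  e <- g@edges
  deg <- stats::setNames(integer(length(genes)), genes)
  str <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(e) > 0) {
    tabA <- tapply(rep(1L, nrow(e)), e$gene_a, sum)
    tabB <- tapply(rep(1L, nrow(e)), e$gene_b, sum)
    deg[names(tabA)] <- deg[names(tabA)] + tabA
    deg[names(tabB)] <- deg[names(tabB)] + tabB
    wA <- tapply(e$weight, e$gene_a, sum)
    wB <- tapply(e$weight, e$gene_b, sum)
    str[names(wA)] <- str[names(wA)] + wA
    str[names(wB)] <- str[names(wB)] + wB
  }
  data.frame(gene = genes, degree = as.integer(deg[genes]),
             connectivity = rowSums(g@tom)[genes] - 1,
             strength = str[genes], row.names = NULL,
             stringsAsFactors = FALSE)
}

.hubsByQuantile <- function(scores, topFraction, method, extra = list()) {
  cut <- stats::quantile(scores, 1 - topFraction, names = FALSE)
  new("HubResult", method = method, scores = scores,
      hubs = names(scores)[scores >= cut],
      selectionRule = c(list(top_fraction = topFraction, cutoff = cut), extra))
}

#' Hub genes by connectivity
#'
#' Scores every gene by its whole-network connectivity
#' `k_i = sum_{j != i} T_ij` and selects genes at or above the
#' `1 - topFraction` empirical quantile (ties at the cut included). A
#' threshold-based selection adapts the hub count to the network, unlike
#' fixed top-N rules.
#'
#' @param build a [NetworkBuild-class].
#' @param topFraction fraction of genes to select (default 0.05).
#' @return A [HubResult-class].
#' @export
hubsConnectivity <- function(build, topFraction = 0.05) {
  if (topFraction <= 0 || topFraction > 1) stop("topFraction must lie in (0, 1]")
  k <- rowSums(tomMatrix(build)) - 1
  .hubsByQuantile(k, topFraction, "connectivity")
}

#' Hub genes by degree
#'
#' As [hubsConnectivity()] but on the edge-filtered degree of a
#' [GraphView-class].
#'
#' @param g a [GraphView-class].
#' @param topFraction fraction of genes to select (default 0.05).
#' @return A [HubResult-class].
#' @export
hubsDegree <- function(g, topFraction = 0.05) {
  if (topFraction <= 0 || topFraction > 1) stop("topFraction must lie in (0, 1]")
  nm <- nodeMetrics(g)
  deg <- stats::setNames(as.numeric(nm$degree), nm$gene)
  .hubsByQuantile(deg, topFraction, "degree",
                  list(edge_min = g@edgeMin))
}

# shifted power iteration for the principal eigenvector of a symmetric
# non-negative matrix; the diagonal shift (max row sum) guarantees
# convergence even on bipartite-like structures where the raw iteration
# would oscillate between the +/- lambda_max eigenvectors
.principalEigenvector <- function(W, tol = 1e-10, maxIter = 10000) {
  n <- nrow(W)
  if (max(W) == 0) return(list(vector = rep(0, n), iterations = 0L))
  shift <- max(rowSums(W))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(maxIter)) {
    w <- W %*% v + shift * v
    w <- as.vector(w) / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) return(list(vector = abs(w), iterations = it))
    v <- w
  }
  stop("power iteration did not converge in ", maxIter, " iterations")
}

#' Hub genes by Kleinberg score
#'
#' The Kleinberg (HITS) hub score of an undirected weighted graph is the
#' principal eigenvector of its symmetric weight matrix, computed here by
#' power iteration (tolerance 1e-10, at most 10000 iterations) and
#' normalized to maximum 1. Genes scoring at least `scoreFloor` are hubs.
#'
#' @param x a [NetworkBuild-class] or a symmetric weight matrix (TOM) with
#'   gene ids as dimnames.
#' @param scoreFloor hub threshold as a fraction of the maximum score
#'   (default 0.90).
#' @param moduleRestrict optional module id; requires `partition`.
#' @param partition [ModulePartition-class] when restricting to a module.
#' @return A [HubResult-class]; `selectionRule$iterations` records the
#'   power-iteration count.
#' @export
setGeneric("hubsKleinberg",
           function(x, scoreFloor = 0.90, moduleRestrict = NULL,
                    partition = NULL) standardGeneric("hubsKleinberg"))

#' @rdname hubsKleinberg
#' @export
setMethod("hubsKleinberg", "matrix",
          function(x, scoreFloor = 0.90, moduleRestrict = NULL,
                   partition = NULL) {
  .checkSymmetric(x, "weight matrix")
  W <- x
  diag(W) <- 0
  pe <- .principalEigenvector(W)
  scores <- pe$vector
  if (max(scores) > 0) scores <- scores / max(scores)
  names(scores) <- colnames(x)
  new("HubResult", method = "kleinberg", scores = scores,
      hubs = names(scores)[scores >= scoreFloor],
      selectionRule = list(score_floor = scoreFloor,
                           iterations = pe$iterations))
})

#' @rdname hubsKleinberg
#' @export
setMethod("hubsKleinberg", "NetworkBuild",
          function(x, scoreFloor = 0.90, moduleRestrict = NULL,
                   partition = NULL) {
  tom <- tomMatrix(x)
  if (!is.null(moduleRestrict)) {
    if (is.null(partition)) stop("module restriction requires a partition")
    labels <- moduleLabels(partition)
    genes <- names(labels)[labels == moduleRestrict]
    if (length(genes) == 0) stop("unknown module id: ", moduleRestrict)
    tom <- tom[genes, genes, drop = FALSE]
  }
  hubsKleinberg(tom, scoreFloor = scoreFloor)
})

#' Sub-module detection by PAM and silhouette
#'
#' Partitions one module on its TOM dissimilarity `d = 1 - T` with k-medoids
#' (PAM, deterministic BUILD + SWAP), choosing the number of sub-modules k
#' that maximizes the mean silhouette width over `kRange`. If the best mean
#' silhouette stays below `silhouetteFloor` the module is reported as having
#' no reliable substructure (k = 1); modules with fewer than 4 genes return
#' k = 1 with a warning.
#'
#' @param x a [NetworkBuild-class] (with `partition` and `moduleId`) or a
#'   TOM submatrix over the module's genes.
#' @param partition [ModulePartition-class] (NetworkBuild method).
#' @param moduleId module to analyse (NetworkBuild method).
#' @param kRange candidate sub-module counts (default `2:min(15, m - 1)`).
#' @param silhouetteFloor minimum mean silhouette width to accept
#'   substructure (default 0.20).
#' @param seed unused by the deterministic PAM; kept for interface stability.
#' @return A [SubModulePartition-class].
#' @export
setGeneric("detectSubmodules",
           function(x, partition = NULL, moduleId = NULL, kRange = NULL,
                    silhouetteFloor = 0.20, seed = NULL)
             standardGeneric("detectSubmodules"))

#' @rdname detectSubmodules
#' @export
setMethod("detectSubmodules", "matrix",
          function(x, partition = NULL, moduleId = NULL, kRange = NULL,
                   silhouetteFloor = 0.20, seed = NULL) {
  .checkSymmetric(x, "tom")
  genes <- colnames(x)
  m <- length(genes)
  modId <- if (is.null(moduleId)) NA_integer_ else as.integer(moduleId)
  if (m < 4) {
    warning("module has fewer than 4 genes; no sub-module search performed",
            call. = FALSE)
    medoid <- genes[which.min(rowSums(1 - x))]
    return(new("SubModulePartition", moduleId = modId, k = 1L,
               subLabels = stats::setNames(rep(1L, m), genes),
               silhouetteByK = numeric(0), medoids = medoid))
  }
  d <- stats::as.dist(1 - x)
  if (is.null(kRange)) kRange <- 2:min(15, m - 1)
  kRange <- kRange[kRange >= 2 & kRange <= m - 1]
  fits <- lapply(kRange, function(k) cluster::pam(d, k, diss = TRUE))
  sil <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1))
  names(sil) <- as.character(kRange)
  best <- which.max(sil)
  if (length(best) == 0 || sil[best] < silhouetteFloor) {
    medoid <- genes[which.min(rowSums(1 - x))]
    return(new("SubModulePartition", moduleId = modId, k = 1L,
               subLabels = stats::setNames(rep(1L, m), genes),
               silhouetteByK = sil, medoids = medoid))
  }
  fit <- fits[[best]]
  new("SubModulePartition", moduleId = modId,
      k = as.integer(kRange[best]),
      subLabels = stats::setNames(as.integer(fit$clustering), genes),
      silhouetteByK = sil, medoids = genes[fit$id.med])
})

#' @rdname detectSubmodules
#' @export
setMethod("detectSubmodules", "NetworkBuild",
          function(x, partition = NULL, moduleId = NULL, kRange = NULL,
                   silhouetteFloor = 0.20, seed = NULL) {
  if (is.null(partition) || is.null(moduleId))
    stop("partition and moduleId are required")
  labels <- moduleLabels(partition)
  genes <- names(labels)[labels == moduleId]
  if (length(genes) == 0) stop("unknown module id: ", moduleId)
  tom <- tomMatrix(x)[genes, genes, drop = FALSE]
  detectSubmodules(tom, moduleId = moduleId, kRange = kRange,
                   silhouetteFloor = silhouetteFloor, seed = seed)
})
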