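# Independent oracles and fixture builders used across the suite. Oracles are
# deliberately naive (loops, enumeration, dense solvers) and share no code
# with the implementation paths they check.

rndAdj <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# triple-loop TOM evaluation
naiveTom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- diag(n)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    u <- setdiff(1:n, c(i, j))
    L <- sum(a[i, u] * a[u, j])
    tom[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# O(n^3) average-linkage agglomeration returning merge heights
naiveAvgLinkHeights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      v <- mean(d[clusters[[i]], clusters[[j]]])
      if (v < bestv) { bestv <- v; best <- c(j, i) }
    }
    heights <- c(heights, bestv)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# hypergeometric upper tail by direct combinatorial enumeration
enumHyperP <- function(N, K, n, x) {
  ks <- x:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# block-structured TOM-like similarity matrix with optional symmetric noise
blockTom <- function(sizes, within, across, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sum(sizes)
  tom <- matrix(across, m, m)
  pos <- 0
  for (s in sizes) {
    idx <- pos + seq_len(s)
    tom[idx, idx] <- within
    pos <- pos + s
  }
  if (noise > 0) {
    eps <- matrix(stats::rnorm(m * m, 0, noise), m, m)
    tom <- tom + (eps + t(eps)) / 2
  }
  tom <- pmin(pmax(tom, 0), 1)
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:m), sprintf("g%02d", 1:m))
  tom
}

# minimal valid NetworkBuild wrapping a given similarity matrix
buildFromTom <- function(tom) {
  new("NetworkBuild", geneIds = colnames(tom), corMethod = "pearson",
      networkType = "unsigned", correlation = tom, power = 1,
      fitTable = data.frame(), adjacency = tom, tom = tom,
      metadata = list(synthetic = TRUE))
}

# definitional (loop-based) recomputation of the seven preservation
# statistics; discovery quantities come from moduleGenes, test quantities
# from testGenes (defaults to the module itself)
naivePreservation <- function(dsD, bD, dsT, bT, moduleGenes,
                              testGenes = moduleGenes) {
  m <- length(moduleGenes)
  cD <- correlationMatrix(bD)[moduleGenes, moduleGenes]
  wD <- tomMatrix(bD)[moduleGenes, moduleGenes]
  cT <- correlationMatrix(bT)[testGenes, testGenes]
  wT <- tomMatrix(bT)[testGenes, testGenes]
  hD <- computeEigengene(dsD, moduleGenes)$eigengene
  hT <- computeEigengene(dsT, testGenes)$eigengene
  nuD <- vapply(moduleGenes,
                function(g) stats::cor(exprValues(dsD)[, g], hD), numeric(1))
  nuT <- vapply(testGenes,
                function(g) stats::cor(exprValues(dsT)[, g], hT), numeric(1))
  s <- unname(ifelse(nuD >= 0, 1, -1))
  aw <- 0; ac <- 0
  for (i in 1:m) for (j in 1:m) if (i != j) {
    aw <- aw + wT[i, j]
    ac <- ac + cT[i, j] * s[i] * s[j]
  }
  kD <- vapply(1:m, function(i) sum(wD[i, -i]), numeric(1))
  kT <- vapply(1:m, function(i) sum(wT[i, -i]), numeric(1))
  od <- function(M) M[lower.tri(M)]
  c(avg.weight = aw / (m * (m - 1)), coherence = mean(nuT^2),
    avg.cor = ac / (m * (m - 1)), avg.contrib = mean(nuT * s),
    cor.cor = stats::cor(od(cD), od(cT)),
    cor.degree = stats::cor(kD, kT),
    cor.contrib = stats::cor(nuD, nuT))
}

# definitionally independent mean silhouette width (double loop)
naiveMeanSilhouette <- function(d, labels) {
  n <- nrow(d)
  sil <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { sil[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

quietRead <- function(...) suppressMessages(suppressWarnings(readExpression(...)))

# small planted dataset helper
plantedSim <- function(nSamples, sizes, nBackground = 0, coherence = 0.9,
                       noiseSd = 0, seed = 1, ...) {
  simulateExpression(simulationConfig(nSamples, moduleSizes = sizes,
                                      nBackground = nBackground,
                                      coherence = coherence, noiseSd = noiseSd,
                                      seed = seed, ...))
}
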