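test_that("gene clustering reproduces naive average-linkage merge heights", {
  # two genes: single merge at 1 - T12
  tom2 <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- clusterGenes(tom2)
  expect_equal(hc2$height, 0.3)

  # two perfect cliques joined at distance 1
  tomB <- blockTom(c(3, 3), 1, 0)
  hcB <- clusterGenes(tomB)
  expect_equal(max(hcB$height), 1)

  tom <- tomFromAdjacency(rndAdj(8, seed = 31))
  hc <- clusterGenes(tom)
  expect_equal(sort(hc$height), sort(naiveAvgLinkHeights(1 - tom)),
               tolerance = 1e-12)
})

test_that("tree cut recovers planted blocks exactly without background", {
  sim <- plantedSim(60, rep(50, 5), 0, coherence = 0.9, noiseSd = 0, seed = 41)
  net <- buildNet(sim$dataset, power = 6)
  dendro <- clusterGenes(tomMatrix(net))
  labels <- cutGeneTree(dendro, sim$dataset)
  expect_equal(ariOf(labels, sim$labels), 1.0)
})

test_that("unstructured data yields no coherent modules", {
  for (s in 1:4) {
    sim <- plantedSim(40, integer(0), 30, seed = 50 + s)
    net <- buildNet(sim$dataset, power = 6)
    labels <- cutGeneTree(clusterGenes(tomMatrix(net)), sim$dataset)
    # most genes stay unassigned, and any module that does emerge from the
    # noise must be incoherent (mean within-module |cor| below 0.3)
    expect_gt(mean(labels == 0), 0.5)
    for (mId in setdiff(unique(labels), 0)) {
      g <- names(labels)[labels == mId]
      cc <- abs(cor(exprValues(sim$dataset)[, g]))
      expect_lt(mean(cc[lower.tri(cc)]), 0.3)
    }
  }
})

test_that("size bound and argument validation in the tree cut", {
  sim <- plantedSim(20, c(5, 5), 0, seed = 61)
  net <- buildNet(sim$dataset, power = 2)
  dendro <- clusterGenes(tomMatrix(net))
  labels <- cutGeneTree(dendro, sim$dataset, minModuleSize = 20)
  expect_true(all(labels == 0))
  expect_error(cutGeneTree(dendro, sim$dataset, minModuleSize = 1), ">= 2")
})

test_that("eigengene has the documented PCA semantics", {
  sim <- plantedSim(50, 30, 5, coherence = 0.8, noiseSd = 0, seed = 71)
  ds <- sim$dataset

  # single gene: z-scored profile, explained variance 1
  e1 <- computeEigengene(ds, "g0001")
  z <- scale(exprValues(ds)[, "g0001"])[, 1]
  expect_equal(unname(e1$eigengene), unname(z), tolerance = 1e-12)
  expect_equal(e1$explainedVariance, 1)

  # two perfectly correlated genes: rank one
  m <- exprValues(ds)
  m2 <- cbind(m, dup = 2 * m[, "g0001"] + 5)
  e2 <- computeEigengene(ExpressionDataset(m2), c("g0001", "dup"))
  expect_equal(e2$explainedVariance, 1, tolerance = 1e-12)
  expect_equal(abs(cor(e2$eigengene, m[, "g0001"])), 1, tolerance = 1e-12)

  # planted module: eigengene recovers the factor
  em <- computeEigengene(ds, names(sim$labels)[sim$labels == 1])
  expect_gte(abs(cor(em$eigengene, sim$factors[, 1])), 0.95)
  # sign anchored to the mean module profile
  expect_gte(cor(em$eigengene, rowMeans(scale(m[, sim$labels == 1]))), 0)

  expect_error(computeEigengene(
    ExpressionDataset(cbind(m[, 1:2], const = rep(1, nrow(m)))),
    c("g0001", "const")), "zero-variance")
})

test_that("modules from the same factor merge; independent ones do not", {
  sim <- plantedSim(60, 60, 0, coherence = 0.9, noiseSd = 0, seed = 81)
  genes <- geneIds(sim$dataset)
  # artificially split one planted module into two label groups
  labels <- stats::setNames(rep(c(1L, 2L), each = 30), genes)
  mp <- mergeCloseModules(sim$dataset, labels)
  expect_equal(max(moduleLabels(mp)), 1L)
  expect_equal(nrow(mergeHistory(mp)), 1)
  expect_gte(mergeHistory(mp)$eigengene_cor[1], 0.75)
  # premerge labels kept, gene count conserved
  expect_equal(sum(moduleLabels(mp) == 1), 60)
  expect_equal(length(unique(moduleLabelsPremerge(mp))), 2)

  sim2 <- plantedSim(60, c(30, 30), 0, coherence = 0.9, noiseSd = 0, seed = 82)
  mp2 <- mergeCloseModules(sim2$dataset, sim2$labels)
  E <- eigengenes(mp2)
  if (ncol(E) == 2) {         # merged only if eigengene cor >= 0.75
    expect_lt(abs(cor(E[, 1], E[, 2])), 0.75)
  } else {
    expect_gte(mergeHistory(mp2)$eigengene_cor[1], 0.75)
  }

  # merge cut 0: nothing merges
  mp0 <- mergeCloseModules(sim$dataset, labels, mergeCut = 0)
  expect_equal(max(moduleLabels(mp0)), 2L)
  expect_error(mergeCloseModules(sim$dataset, labels, mergeCut = 3), "[0, 2]")
})

test_that("detectModules recovers planted partitions with valid contracts", {
  sim <- plantedSim(60, c(50, 40, 30), 0, coherence = 0.9, noiseSd = 0,
                    seed = 91)
  net <- buildNet(sim$dataset, power = 6)
  mp <- detectModules(sim$dataset, net)
  expect_equal(ariOf(moduleLabels(mp), sim$labels), 1.0)

  # labels 1..M by decreasing size
  sizes <- moduleSizes(mp)
  real <- sizes[names(sizes) != "0"]
  expect_false(is.unsorted(rev(real)))
  # merging can only reduce the module count
  expect_gte(length(unique(moduleLabelsPremerge(mp)[moduleLabelsPremerge(mp) > 0])),
             max(moduleLabels(mp)))
  # unit-variance eigengenes
  expect_equal(unname(apply(eigengenes(mp), 2, var)), rep(1, ncol(eigengenes(mp))),
               tolerance = 1e-8)
  # dendrogram retained
  expect_s3_class(geneDendrogram(mp), "hclust")
})

test_that("own-module genes have higher kME than outsiders", {
  sim <- plantedSim(60, c(40, 40), 40, coherence = 0.85, noiseSd = 0.1,
                    seed = 95)
  net <- buildNet(sim$dataset, power = 6)
  mp <- detectModules(sim$dataset, net)
  km <- abs(kme(mp))
  lab <- moduleLabels(mp)
  for (mId in seq_len(max(lab))) {
    inside <- mean(km[names(lab)[lab == mId], mId])
    outside <- mean(km[names(lab)[lab != mId], mId])
    expect_gt(inside, outside)
  }
})
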