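# two independent draws of the same planted structure, built at power 6
makePair <- function(sizes = c(20, 20), nBackground = 20, nSamples = 50,
                     coherence = 0.85, noiseSd = 0.1, seed = 1,
                     perturbation = "none") {
  sp <- simulateConditionPair(simulationConfig(
    nSamples, moduleSizes = sizes, nBackground = nBackground,
    coherence = coherence, noiseSd = noiseSd, seed = seed,
    perturbation = perturbation))
  pair <- conditionPair(sp$discovery$dataset,
                        buildNet(sp$discovery$dataset, power = 6),
                        sp$test$dataset,
                        buildNet(sp$test$dataset, power = 6))
  list(pair = pair, sp = sp)
}

test_that("the seven statistics match a definitional loop recomputation", {
  mk <- makePair(seed = 11)
  pair <- mk$pair
  genes <- names(mk$sp$truth$labels)[mk$sp$truth$labels == 1][1:6]
  got <- preservationStats(pair, genes)
  want <- naivePreservation(mk$sp$discovery$dataset, pair@discoveryBuild,
                            mk$sp$test$dataset, pair@testBuild, genes)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("self-comparison yields exact cross-condition unity", {
  sim <- plantedSim(40, c(15, 15), 10, coherence = 0.85, noiseSd = 0.1,
                    seed = 21)
  net <- buildNet(sim$dataset, power = 6)
  pair <- conditionPair(sim$dataset, net, sim$dataset, net)
  st <- preservationStats(pair, names(sim$labels)[sim$labels == 1])
  expect_identical(unname(st[c("cor.cor", "cor.degree", "cor.contrib")]),
                   c(1, 1, 1))
})

test_that("constant-weight module gives avg.weight equal to that weight", {
  n <- 20
  set.seed(31)
  m <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("g%02d", 1:n)))
  ds <- ExpressionDataset(m)
  tom <- blockTom(n, 0.42, 0.42)
  build <- buildFromTom(tom)
  pair <- conditionPair(ds, build, ds, build)
  st <- preservationStats(pair, colnames(m)[1:8])
  expect_equal(unname(st["avg.weight"]), 0.42, tolerance = 1e-12)
})

test_that("permutation p-values hit the add-one floor for a strong module", {
  mk <- makePair(seed = 41)
  genes <- names(mk$sp$truth$labels)[mk$sp$truth$labels == 1]
  pn <- permutationNull(mk$pair, genes, nPerm = 200, seed = 5)
  expect_equal(unname(pn$pValues["avg.weight"]), 1 / 201)
  expect_true(all(pn$pValues >= 1 / 201))

  # fully determined by the seed
  pn2 <- permutationNull(mk$pair, genes, nPerm = 200, seed = 5)
  expect_identical(pn, pn2)

  expect_warning(permutationNull(mk$pair, genes, nPerm = 50, seed = 1),
                 "fewer than 100")
})

test_that("permutation null matches exhaustive subset enumeration", {
  # 6 shared genes, module of 3: only choose(6, 3) = 20 distinct draws exist
  set.seed(51)
  m1 <- matrix(rnorm(40 * 6), 40, 6,
               dimnames = list(sprintf("s%02d", 1:40), sprintf("g%02d", 1:6)))
  m2 <- matrix(rnorm(40 * 6), 40, 6, dimnames = dimnames(m1))
  dsD <- ExpressionDataset(m1); dsT <- ExpressionDataset(m2)
  bD <- buildNet(dsD, power = 2); bT <- buildNet(dsT, power = 2)
  pair <- conditionPair(dsD, bD, dsT, bT)
  mod <- colnames(m1)[1:3]

  # the cross-condition statistics pair discovery gene i with test gene i,
  # so the null support is all ordered assignments: C(6,3) * 3! tuples
  perms3 <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  tuples <- unlist(lapply(combn(colnames(m1), 3, simplify = FALSE),
                          function(s) lapply(perms3, function(p) s[p])),
                   recursive = FALSE)
  enumStats <- vapply(tuples, function(s)
    naivePreservation(dsD, bD, dsT, bT, mod, testGenes = s),
    numeric(7))
  obs <- naivePreservation(dsD, bD, dsT, bT, mod)

  nPerm <- 4000
  pn <- permutationNull(pair, mod, nPerm = nPerm, seed = 9)
  for (stat in c("avg.weight", "coherence", "cor.cor", "avg.contrib")) {
    # tuples tied with the observed value up to rounding (reorderings of
    # the module itself) can land on either side of the >= comparison, so
    # the exact probability is bracketed rather than pinned
    pLow <- mean(enumStats[stat, ] > obs[stat] + 1e-12)
    pHigh <- mean(enumStats[stat, ] >= obs[stat] - 1e-12)
    mcSd <- sqrt(max(pHigh * (1 - pHigh), pLow * (1 - pLow)) / nPerm)
    expect_gte(pn$pValues[stat], pLow - 3 * mcSd - 2 / nPerm)
    expect_lte(pn$pValues[stat], pHigh + 3 * mcSd + 2 / nPerm)
  }
})

test_that("Z-summary arithmetic follows the median/mean definition", {
  obs <- stats::setNames(c(1, 2, 3, 4, 10, 20, 30),
                         c("avg.weight", "coherence", "avg.cor", "avg.contrib",
                           "cor.cor", "cor.degree", "cor.contrib"))
  zero <- stats::setNames(rep(0, 7), names(obs))
  one <- stats::setNames(rep(1, 7), names(obs))
  z <- zSummaryScore(obs, zero, one)
  expect_equal(z$zDensity, 2.5)
  expect_equal(z$zConnectivity, 20)
  expect_equal(z$zSummary, 11.25)

  # centred observations give zero everywhere
  z0 <- zSummaryScore(obs, obs, one)
  expect_equal(z0$zSummary, 0)

  # zero spread makes a statistic drop out of its median
  sd0 <- one; sd0["avg.weight"] <- 0
  zn <- zSummaryScore(obs, zero, sd0)
  expect_true(is.nan(zn$zScores["avg.weight"]))
  expect_equal(zn$zDensity, 3)     # median of {2, 3, 4}
  # a whole group of NaNs poisons the summary
  sdAll <- one; sdAll[c("cor.cor", "cor.degree", "cor.contrib")] <- 0
  expect_true(is.nan(zSummaryScore(obs, zero, sdAll)$zSummary))
})

test_that("four-way status classification follows the decision rules", {
  p <- stats::setNames(rep(0.001, 7),
                       c("avg.weight", "coherence", "avg.cor", "avg.contrib",
                         "cor.cor", "cor.degree", "cor.contrib"))
  expect_equal(classifyPreservation(p, 0.05, zSummary = 1), "preserved")
  p2 <- p; p2["cor.cor"] <- 0.2
  expect_equal(classifyPreservation(p2, 0.05, zSummary = 1.3), "unpreserved")
  expect_equal(classifyPreservation(p2, 0.05, zSummary = 5),
               "moderately_preserved")
  expect_equal(classifyPreservation(p2, 0.05, zSummary = 25), "inconclusive")
  expect_warning(st <- classifyPreservation(p[1:5], 0.05, 3), "missing")
  expect_equal(st, "inconclusive")
})

test_that("compareConditions is deterministic and skips tiny modules", {
  mk <- makePair(seed = 61)
  mp <- partitionFromLabels(mk$sp$discovery$dataset, mk$sp$truth$labels)
  r1 <- compareConditions(mk$pair, mp, nPerm = 150, seed = 3)
  r2 <- compareConditions(mk$pair, mp, nPerm = 150, seed = 3)
  expect_identical(r1@pValues, r2@pValues)
  expect_identical(r1@status, r2@status)
  expect_true(all(r1@pValues >= 1 / 151, na.rm = TRUE))

  labels <- mk$sp$truth$labels
  labels[labels == 2] <- 0
  labels[names(labels)[1:2]] <- 0   # shrink module 1? no: make a 2-gene module
  tiny <- labels
  tiny[] <- 0L
  tiny[1:2] <- 1L
  mpTiny <- partitionFromLabels(mk$sp$discovery$dataset, tiny)
  expect_warning(compareConditions(mk$pair, mpTiny, nPerm = 100, seed = 1),
                 "skipped")
})

test_that("difference matrix is zero on identical builds and elementwise", {
  sim <- plantedSim(40, c(15, 15), 0, coherence = 0.85, noiseSd = 0.1,
                    seed = 71)
  net <- buildNet(sim$dataset, power = 6)
  pairSelf <- conditionPair(sim$dataset, net, sim$dataset, net)
  expect_true(all(coexpDifference(pairSelf) == 0))

  mk <- makePair(seed = 72)
  d <- coexpDifference(mk$pair)
  g <- sharedGenes(mk$pair)
  want <- tomMatrix(mk$pair@testBuild)[g, g] -
    tomMatrix(mk$pair@discoveryBuild)[g, g]
  diag(want) <- 0
  expect_equal(d, want, tolerance = 1e-15)
  expect_identical(d, t(d))
  # positive where the test condition gained co-expression
  up <- which(d > 0, arr.ind = TRUE)[1, ]
  expect_gt(tomMatrix(mk$pair@testBuild)[g, g][up[1], up[2]],
            tomMatrix(mk$pair@discoveryBuild)[g, g][up[1], up[2]])
})

test_that("difference matrix follows the discovery dendrogram order", {
  sim <- plantedSim(40, c(15, 15), 0, coherence = 0.9, noiseSd = 0, seed = 81)
  net <- buildNet(sim$dataset, power = 6)
  mp <- detectModules(sim$dataset, net)
  pair <- conditionPair(sim$dataset, net, sim$dataset, net)
  d <- coexpDifference(pair, partition = mp)
  hc <- geneDendrogram(mp)
  expect_identical(rownames(d), hc$labels[hc$order])
})
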