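test_that("correlation matches the textbook formula and handles methods", {
  set.seed(10)
  m <- matrix(rnorm(25), 5, 5,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:5)))
  ds <- ExpressionDataset(m)
  r <- correlateExpression(ds)
  x <- m[, 1]; y <- m[, 2]
  rManual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["g1", "g2"], rManual, tolerance = 1e-12)

  # duplicated gene profile -> r = 1
  m2 <- cbind(m, g6 = m[, 1])
  expect_equal(correlateExpression(ExpressionDataset(m2))["g1", "g6"], 1)

  # monotone transform: spearman saturates, pearson does not
  m3 <- cbind(x = c(1, 2, 3, 4), y = exp(c(1, 2, 3, 4)),
              z = c(2, 1, 4, 3))
  rownames(m3) <- paste0("s", 1:4)
  ds3 <- ExpressionDataset(m3)
  expect_equal(correlateExpression(ds3, "spearman")["x", "y"], 1)
  expect_lt(correlateExpression(ds3, "pearson")["x", "y"], 1)
})

test_that("correlation rejects degenerate input", {
  m <- cbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 0, 1))
  rownames(m) <- paste0("s", 1:3)
  expect_error(correlateExpression(ExpressionDataset(m)), "zero-variance.*a")
  m2 <- matrix(rnorm(4), 2, 2,
               dimnames = list(paste0("s", 1:2), paste0("g", 1:2)))
  expect_error(correlateExpression(ExpressionDataset(m2)), ">= 3 samples")
})

# correlation whose adjacency has a power-law connectivity distribution by
# construction: a_ij = x_i x_j with x heavy-tailed, so k_i tracks x_i
scaleFreeCor <- function(n = 60, beta0 = 6, seed = 7) {
  set.seed(seed)
  x <- (1 - runif(n))^(-1 / 2.5)
  x <- x / max(x)
  a <- outer(x, x)
  r <- a^(1 / beta0)
  diag(r) <- 1
  dimnames(r) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  r
}

# independent re-computation of one fit-table row using hist() binning
oracleFitRow <- function(correlation, beta, nBins = 10) {
  a <- abs(correlation)^beta
  diag(a) <- 0
  k <- rowSums(a)
  h <- hist(k, breaks = seq(min(k), max(k), length.out = nBins + 1),
            plot = FALSE)
  bin <- findInterval(k, h$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  meanK <- tapply(k, bin, mean)
  freq <- as.numeric(table(factor(bin, levels = seq_len(nBins)))) / length(k)
  use <- freq > 0 & !is.na(meanK[as.character(seq_len(nBins))])
  mk <- meanK[as.character(seq_len(nBins))][use]
  fr <- freq[use]
  keep <- mk > 0
  fit <- lm(log10(fr[keep]) ~ log10(mk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

test_that("soft power selection agrees with an independent binned regression", {
  r <- scaleFreeCor()
  res <- fitSoftPower(r, r2Cut = 0.85)
  tab <- res$fitTable
  # smallest passing power is returned
  expect_equal(res$power, min(tab$power[!is.na(tab$r2_signed) &
                                          tab$r2_signed >= 0.85]))
  # chosen row agrees with the oracle regression
  row <- tab[tab$power == res$power, ]
  expect_equal(row$r2_signed, unname(oracleFitRow(r, res$power)),
               tolerance = 1e-8)
  # vacuous cut returns the smallest candidate
  expect_equal(fitSoftPower(r, r2Cut = 0)$power, 1)
})

test_that("degenerate and aberrant connectivity distributions are errors", {
  flat <- blockTom(12, 0.5, 0.5)  # all off-diagonals equal -> single bin
  expect_error(fitSoftPower(flat), "usable bins")

  set.seed(8)   # unstructured noise correlations never fit a power law well
  m <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("g%02d", 1:40)))
  r <- correlateExpression(ExpressionDataset(m))
  err <- tryCatch(fitSoftPower(r, r2Cut = 0.999), error = identity)
  expect_s3_class(err, "coexpnet_aberrant_power")
  expect_true(is.data.frame(err$fitTable))
  expect_equal(nrow(err$fitTable), 30)
})

test_that("adjacency is |r|^beta with unit diagonal and monotone in |r|", {
  r <- matrix(c(1, -0.5, -0.5, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(adjacencyFromCor(r, 2)["a", "b"], 0.25)
  expect_equal(adjacencyFromCor(r, 1)["a", "b"], 0.5)

  set.seed(9)
  rr <- cor(matrix(rnorm(200), 20, 10))
  dimnames(rr) <- list(paste0("g", 1:10), paste0("g", 1:10))
  a <- adjacencyFromCor(rr, 4)
  expect_equal(a[upper.tri(a)], abs(rr[upper.tri(rr)])^4, tolerance = 1e-14)
  ord <- order(abs(rr[upper.tri(rr)]))
  expect_false(is.unsorted(a[upper.tri(a)][ord]))
  # increasing beta weakly decreases every off-diagonal entry
  a6 <- adjacencyFromCor(rr, 6)
  expect_true(all(a6[upper.tri(a6)] <= a[upper.tri(a)] + 1e-15))
})

test_that("TOM matches the brute-force triple loop and honors edge cases", {
  a <- rndAdj(10, seed = 12)
  expect_equal(tomFromAdjacency(a), naiveTom(a), tolerance = 1e-12)

  # no connections
  eye <- diag(4)
  dimnames(eye) <- list(paste0("g", 1:4), paste0("g", 1:4))
  t0 <- tomFromAdjacency(eye)
  expect_true(all(t0[upper.tri(t0)] == 0))

  # saturated clique: T = (1 + 1) / (2 + 1 - 1) = 1
  ones <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  expect_true(all(tomFromAdjacency(ones) == 1))

  expect_error(tomFromAdjacency(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("TOM invariants hold over random instances", {
  for (s in 1:10) {
    n <- sample(5:30, 1)
    tom <- tomFromAdjacency(rndAdj(n, seed = 100 + s))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_identical(tom, t(tom))
    expect_true(all(diag(tom) == 1))
  }
})

test_that("buildNet composes the steps with provenance and rank invariance", {
  sim <- plantedSim(40, c(30, 30), 40, coherence = 0.85, noiseSd = 0.1,
                    seed = 21)
  net <- buildNet(sim$dataset, power = 6)
  expect_s4_class(net, "NetworkBuild")
  expect_equal(buildMetadata(net)$cor_method, "pearson")
  expect_equal(buildMetadata(net)$power, 6)
  expect_identical(geneIds(net), geneIds(sim$dataset))

  # monotone per-gene transform leaves the spearman TOM unchanged
  m <- exprValues(sim$dataset)
  dsT <- ExpressionDataset(exp(m / 2))
  n1 <- buildNet(sim$dataset, corMethod = "spearman", power = 6)
  n2 <- buildNet(dsT, corMethod = "spearman", power = 6)
  expect_equal(tomMatrix(n1), tomMatrix(n2), tolerance = 1e-12)
})
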