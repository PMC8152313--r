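# small helper: a partition over a known gene universe with given modules
labelPartition <- function(moduleList, universe, nSamples = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nSamples * length(universe)), nSamples, length(universe),
              dimnames = list(sprintf("s%03d", seq_len(nSamples)), universe))
  labels <- stats::setNames(rep(0L, length(universe)), universe)
  for (i in seq_along(moduleList)) labels[moduleList[[i]]] <- i
  partitionFromLabels(ExpressionDataset(m), labels)
}

test_that("ORA p-values equal combinatorial enumeration", {
  universe <- sprintf("g%02d", 1:20)
  mod <- universe[1:5]
  gsc <- GeneSetCollection(list(T1 = universe[1:5]))
  part <- labelPartition(list(mod), universe)
  res <- oraEnrich(part, gsc, minTerm = 2)
  # all 5 module genes hit the 5-gene term in a 20-gene universe
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 6.449948e-05, tolerance = 1e-4)

  set.seed(33)
  for (r in 1:50) {
    N <- sample(8:25, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    gsc <- GeneSetCollection(list(T = sample(uni, K)))
    part <- labelPartition(list(sample(uni, n)), uni, seed = r)
    res <- oraEnrich(part, gsc, minTerm = 1, maxTerm = 1000)
    x <- res$overlap_count
    expect_equal(res$p_value, enumHyperP(N, K, n, x), tolerance = 1e-12)
  }
})

test_that("ORA upper tail from zero overlap covers all outcomes", {
  universe <- sprintf("g%02d", 1:15)
  gsc <- GeneSetCollection(list(T1 = universe[11:15]))
  part <- labelPartition(list(universe[1:5]), universe)
  res <- oraEnrich(part, gsc, minTerm = 2)
  expect_equal(res$overlap_count, 0)
  expect_equal(res$p_value, 1)   # tail from x = 0 sums the whole support
})

test_that("module 0 is never tested and term-size bounds apply", {
  universe <- sprintf("g%02d", 1:30)
  gsc <- GeneSetCollection(list(small = universe[1:2],
                                ok = universe[1:10],
                                big = universe))
  part <- labelPartition(list(universe[1:8]), universe)
  res <- oraEnrich(part, gsc, minTerm = 5, maxTerm = 20)
  expect_setequal(unique(res$term_id), "ok")
  expect_true(all(res$module >= 1))
})

test_that("custom background is intersected with a warning", {
  universe <- sprintf("g%02d", 1:20)
  gsc <- GeneSetCollection(list(T1 = universe[1:6]))
  part <- labelPartition(list(universe[1:5]), universe)
  expect_warning(res <- oraEnrich(part, gsc, background = universe[3:20],
                                  minTerm = 2), "outside the background")
  expect_equal(res$term_size, 4)  # T1 restricted to the background
  expect_equal(res$overlap_count, 3)
})

test_that("BH adjustment preserves the raw p-value ordering", {
  set.seed(44)
  universe <- sprintf("g%02d", 1:25)
  gsc <- GeneSetCollection(list(A = sample(universe, 8),
                                B = sample(universe, 10),
                                C = sample(universe, 6)))
  part <- labelPartition(list(sample(universe, 7), sample(universe, 9)),
                         universe)
  res <- oraEnrich(part, gsc, minTerm = 2)
  ord <- order(res$p_value)
  expect_false(is.unsorted(res$adjusted_p[ord]))
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("dummy encoding keeps every level and passes binaries through", {
  enc <- dummyEncode(c("A", "B", "C", "A"), "var")
  expect_equal(colnames(enc), c("var=A", "var=B", "var=C"))
  expect_equal(enc[, "var=A"], c(1, 0, 0, 1))

  enc2 <- dummyEncode(c("A", "A", "B"), "v")
  expect_equal(unname(enc2[, "v=A"]), c(1, 1, 0))

  bin <- dummyEncode(c(0, 1, 1, 0), "b")
  expect_equal(ncol(bin), 1)
  expect_equal(unname(bin[, 1]), c(0, 1, 1, 0))

  expect_error(dummyEncode(c("A", "A"), "v"), ">= 2")
})

test_that("phenotype association recovers exact and point-biserial effects", {
  sim <- plantedSim(50, 30, 0, coherence = 0.9, noiseSd = 0, seed = 55)
  mp <- partitionFromLabels(sim$dataset, sim$labels)
  e <- eigengenes(mp)[, "ME1"]

  # phenotype equal to the eigengene: r = 1, p = 0
  ph <- data.frame(exact = e, row.names = sampleIds(sim$dataset))
  res <- associatePhenotypes(mp, ph)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 0)

  # binary phenotype: r is the point-biserial correlation
  grp <- ifelse(e > median(e), "high", "low")
  ph2 <- data.frame(group = grp, row.names = sampleIds(sim$dataset),
                    stringsAsFactors = FALSE)
  res2 <- associatePhenotypes(mp, ph2)
  ind <- as.numeric(grp == "high")
  n1 <- sum(ind); n0 <- sum(1 - ind); n <- length(ind)
  pb <- (mean(e[ind == 1]) - mean(e[ind == 0])) / sd(e) *
    sqrt(n1 * n0 / (n * (n - 1)))
  expect_equal(res2$r[res2$level == "high"], pb, tolerance = 1e-12)
  expect_equal(res2$r[res2$level == "low"], -pb, tolerance = 1e-12)
})

test_that("association is invariant to consistent sample reordering", {
  sim <- plantedSim(40, c(20, 20), 0, coherence = 0.85, noiseSd = 0.1,
                    seed = 66)
  mp <- partitionFromLabels(sim$dataset, sim$labels)
  set.seed(1)
  ph <- data.frame(y = rnorm(40), row.names = sampleIds(sim$dataset))
  r1 <- associatePhenotypes(mp, ph)

  perm <- sample(40)
  dsPerm <- ExpressionDataset(exprValues(sim$dataset)[perm, , drop = FALSE])
  mpPerm <- partitionFromLabels(dsPerm, sim$labels)
  r2 <- associatePhenotypes(mpPerm, ph[sampleIds(dsPerm), , drop = FALSE])
  expect_equal(abs(r1$r), abs(r2$r), tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("zero-variance phenotypes are skipped with a warning", {
  sim <- plantedSim(30, 20, 0, seed = 77)
  mp <- partitionFromLabels(sim$dataset, sim$labels)
  ph <- data.frame(flat = rep(1, 30), y = rnorm(30),
                   row.names = sampleIds(sim$dataset))
  expect_warning(res <- associatePhenotypes(mp, ph), "zero-variance")
  expect_setequal(unique(res$variable), "y")
})
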